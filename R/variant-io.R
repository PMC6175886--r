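VARIANT_COLS <- c("contig", "pos", "ref", "alt", "qual", "depth", "strain")

#' Construct a variant table
#'
#' A variant table is a data frame of single-nucleotide variants with columns
#' `contig`, `pos` (1-based), `ref`, `alt` (single bases), `qual`
#' (phred-like), `depth` (read count) and `strain`.
#'
#' @param contig,pos,ref,alt,qual,depth,strain Column vectors (recycled).
#' @return A `variant_table` data frame.
#' @export
variant_table <- function(contig = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          qual = numeric(0), depth = integer(0),
                          strain = character(0)) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   qual = as.numeric(qual), depth = as.integer(depth),
                   strain = as.character(strain),
                   stringsAsFactors = FALSE)
  validate_variant_table(df)
}

validate_variant_table <- function(df) {
  if (nrow(df) > 0) {
    bad <- which(df$ref == df$alt | nchar(df$ref) != 1L |
                   nchar(df$alt) != 1L | df$pos < 1L)
    if (length(bad))
      stop("invalid variant record(s) at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

variant_key <- function(tab) {
  paste(tab$contig, tab$pos, tab$ref, tab$alt, sep = ":")
}

#' Load per-strain variants from VCF or the tab-separated dialect
#'
#' VCF v4.2 files (detected by a `##fileformat` header) are parsed with
#' \pkg{vcfR}; biallelic SNV records are kept, and multi-allelic or
#' non-SNV lines are skipped with their count recorded in the `skipped`
#' attribute (and a message). Files without a VCF header are read as the
#' tab-separated dialect written by [write_variants_tsv()].
#'
#' @param path Input file.
#' @param strain Strain label to attach; defaults to the file's base name
#'   for VCF input (or the file's own `strain` column for TSV input).
#' @return A `variant_table`; attribute `skipped` counts non-SNV lines.
#' @export
load_variants <- function(path, strain = NULL) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "##fileformat=VCF")) {
    load_variants_vcf(path, strain)
  } else {
    load_variants_tsv(path, strain)
  }
}

load_variants_vcf <- function(path, strain) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- variant_table()
    attr(out, "skipped") <- 0L
    return(out)
  }
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  dp[is.na(dp)] <- 0L
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% BASES & fix$ALT %in% BASES
  n_skip <- sum(!is_snv)
  if (n_skip > 0)
    message("load_variants: skipped ", n_skip, " non-SNV record(s) in ",
            basename(path))
  if (is.null(strain))
    strain <- sub("\\.vcf$", "", basename(path))
  out <- variant_table(
    contig = fix$CHROM[is_snv],
    pos = as.integer(fix$POS[is_snv]),
    ref = fix$REF[is_snv], alt = fix$ALT[is_snv],
    qual = suppressWarnings(as.numeric(fix$QUAL[is_snv])),
    depth = dp[is_snv], strain = strain
  )
  attr(out, "skipped") <- n_skip
  out
}

load_variants_tsv <- function(path, strain) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(VARIANT_COLS, names(df))
  if (length(missing_cols))
    stop("malformed variant TSV ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    toupper(df$ref) %in% BASES & toupper(df$alt) %in% BASES
  n_skip <- sum(!is_snv)
  if (n_skip > 0)
    message("load_variants: skipped ", n_skip, " non-SNV record(s) in ",
            basename(path))
  bad <- which(is_snv & (toupper(df$ref) == toupper(df$alt) | df$pos < 1L))
  if (length(bad))
    stop("malformed variant TSV ", basename(path), ": invalid record at line ",
         bad[1] + 1L)  # +1 for the header line
  df <- df[is_snv, VARIANT_COLS]
  if (!is.null(strain)) df$strain <- strain
  out <- validate_variant_table(df)
  attr(out, "skipped") <- n_skip
  rownames(out) <- NULL
  out
}

#' Write a variant table as VCF v4.2
#'
#' Emits one SNV per record with CHROM/POS/ID/REF/ALT/QUAL/FILTER and read
#' depth in `INFO` as `DP=`; coordinates are 1-based as in the input table.
#'
#' @param tab A `variant_table` (one strain).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(tab, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polyswitch",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ord <- order(tab$contig, tab$pos)
  tab <- tab[ord, , drop = FALSE]
  body <- if (nrow(tab)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%.6g\t.\tDP=%d",
            tab$contig, tab$pos, tab$ref, tab$alt, tab$qual, tab$depth)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a variant table in the tab-separated dialect
#'
#' @param tab A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[, VARIANT_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
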