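## Readers and writers for the pipeline's plain-text formats.

#' Read/write tab-separated allele-count tables
#'
#' Columns: `population`, `chrom`, `pos`, `ref`, `alt`, `timepoint`,
#' `ref_reads`, `alt_reads`.
#' @param path File path.
#' @return data.frame (reader) or invisible path (writer).
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(population = "character",
                                         chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  check_count_table(df)
  df
}

#' @rdname read_allele_counts
#' @param table Allele-count table to write.
#' @export
write_allele_counts <- function(table, path) {
  check_count_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-site depth table (`chrom`, `pos`, `depth`)
#' @param path File path.
#' @return data.frame.
#' @export
read_depth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "depth")
  if (!all(need %in% names(df)))
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a BED mask into the package's mask convention
#'
#' BED intervals are 0-based half-open `[start, end)`; call positions are
#' 1-based. The returned mask uses the half-open-on-position convention of
#' [apply_region_exclusions()], i.e. a returned row (`start`, `end`) masks
#' 1-based positions `start <= pos < end` and covers exactly the bases the
#' BED record covers.
#'
#' @param path BED file path (no header; at least chrom/start/end columns).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]) + 1L,
             end = as.integer(df[[3]]) + 1L, stringsAsFactors = FALSE)
}

#' Read per-sample allele depths from a VCF
#'
#' Extracts the AD (allele depth) field for every sample and returns the
#' long allele-count table the calling functions consume. Multi-allelic
#' records are split into one biallelic row per alternate allele; the
#' reference count of each row is the AD reference entry.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_map Optional data.frame mapping VCF sample names to
#'   populations and timepoints (`sample`, `population`, `timepoint`).
#'   Without it, each sample becomes its own population at timepoint 1.
#' @return Allele-count table (see [read_allele_counts()]).
#' @export
read_vcf_allele_depths <- function(path, sample_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(population = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), timepoint = integer(0),
                      ref_reads = integer(0), alt_reads = integer(0))
  if (nrow(vcf@fix) == 0) return(empty)
  fmt <- vcf@gt[, 1]
  has_ad <- vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, TRUE)
  if (any(!has_ad)) {
    bad <- which(!has_ad)[1]
    stop(sprintf("missing AD field at %s:%s", vcf@fix[bad, "CHROM"],
                 vcf@fix[bad, "POS"]))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(ad)
  if (is.null(sample_map))
    sample_map <- data.frame(sample = samples, population = samples,
                             timepoint = 1L, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(vcf@fix))) {
    alts <- strsplit(vcf@fix[i, "ALT"], ",")[[1]]
    for (s in samples) {
      depths <- suppressWarnings(as.integer(strsplit(ad[i, s], ",")[[1]]))
      if (all(is.na(depths))) next
      depths[is.na(depths)] <- 0L
      meta <- sample_map[sample_map$sample == s, , drop = FALSE]
      if (!nrow(meta)) stop("sample not in sample_map: ", s)
      for (a in seq_along(alts)) {
        rows[[length(rows) + 1]] <- data.frame(
          population = meta$population[1], chrom = vcf@fix[i, "CHROM"],
          pos = as.integer(vcf@fix[i, "POS"]), ref = vcf@fix[i, "REF"],
          alt = alts[a], timepoint = as.integer(meta$timepoint[1]),
          ref_reads = depths[1],
          alt_reads = if (length(depths) > a) depths[a + 1] else 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a gene-model table (`gene`, `target_size`, optionally `aa_length`)
#' @param path File path.
#' @return data.frame.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "target_size") %in% names(df)))
    stop("gene-model table must have columns gene and target_size")
  df
}

#' Read a fluctuation-assay count table (`strain`, `culture`, `count`)
#' @param path File path.
#' @return data.frame.
#' @export
read_fluctuation_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("strain", "count") %in% names(df)))
    stop("fluctuation table must have columns strain and count")
  df
}

## Small stable content hash (FNV-1a over the serialized object) used to
## stamp outputs with the configuration that produced them.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    ## xor on the low 16 bits only (b < 256), keeping h a double < 2^32
    h <- (h %/% 65536) * 65536 + bitwXor(as.integer(h %% 65536), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
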