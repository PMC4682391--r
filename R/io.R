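# File formats: paired-chain FASTA, TSV manifests, matrices and reports.

#' Read a two-chain-per-complex FASTA file
#'
#' Each complex contributes two records named `<complex_id>_A` and
#' `<complex_id>_B`. Affinity values are not carried by FASTA; pair the
#' result with a manifest or set `kd`/`pkd` afterwards.
#'
#' @param path FASTA file path.
#' @return complex records data.frame (`complex_id`, `chain_a`, `chain_b`,
#'   `kd`, `pkd`, `label`), in order of first appearance.
#' @export
read_complex_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (!all(grepl("_[AB]$", nm))) {
    fail("FASTA record names must end in _A or _B (found: %s)",
         paste(head(nm[!grepl("_[AB]$", nm)], 3), collapse = ", "))
  }
  ids <- sub("_[AB]$", "", nm)
  chain <- sub("^.*_", "", nm)
  uids <- unique(ids)
  a <- character(length(uids)); b <- character(length(uids))
  for (i in seq_along(uids)) {
    ia <- which(ids == uids[i] & chain == "A")
    ib <- which(ids == uids[i] & chain == "B")
    if (length(ia) != 1 || length(ib) != 1) {
      fail("complex '%s' must have exactly one _A and one _B record", uids[i])
    }
    a[i] <- as.character(seqs[[ia]])
    b[i] <- as.character(seqs[[ib]])
  }
  data.frame(complex_id = uids, chain_a = a, chain_b = b,
             kd = NA_real_, pkd = NA_real_, label = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write complexes to two-record-per-complex FASTA
#'
#' @param records complex records data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_complex_fasta <- function(records, path) {
  records <- validate_records(records)
  seqs <- as.character(rbind(records$chain_a, records$chain_b))
  names(seqs) <- as.character(rbind(paste0(records$complex_id, "_A"),
                                    paste0(records$complex_id, "_B")))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read or write a complex manifest (TSV)
#'
#' A manifest is a tab-separated table with columns `complex_id`,
#' `chain_a`, `chain_b` and optionally `kd_molar`, `pkd` and `label`.
#' Missing `pkd` is derived from `kd_molar` as -log10(Kd) and vice versa;
#' a missing `label` is derived from Kd when available. A label that
#' contradicts the Kd threshold is an error.
#'
#' @param path TSV file path.
#' @return complex records data.frame.
#' @export
read_complex_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("complex_id", "chain_a", "chain_b")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    fail("manifest %s is missing column(s): %s", path,
         paste(miss, collapse = ", "))
  }
  kd <- if ("kd_molar" %in% names(df)) as.numeric(df$kd_molar) else NA_real_
  pkd <- if ("pkd" %in% names(df)) as.numeric(df$pkd) else NA_real_
  pkd <- ifelse(is.na(pkd) & !is.na(kd), -log10(kd), pkd)
  kd <- ifelse(is.na(kd) & !is.na(pkd), 10^(-pkd), kd)
  label <- if ("label" %in% names(df)) df$label else NA_character_
  label[!nzchar(trimws(as.character(label)))] <- NA
  derivable <- is.na(label) & !is.na(kd)
  label[derivable] <- label_from_kd(kd[derivable])
  records <- data.frame(complex_id = df$complex_id,
                        chain_a = df$chain_a, chain_b = df$chain_b,
                        kd = kd, pkd = pkd, label = label,
                        stringsAsFactors = FALSE)
  validate_records(records)
}

#' @rdname read_complex_manifest
#' @param records complex records data.frame.
#' @return `write_complex_manifest()`: `path`, invisibly.
#' @export
write_complex_manifest <- function(records, path) {
  records <- validate_records(records)
  out <- data.frame(complex_id = records$complex_id,
                    chain_a = records$chain_a, chain_b = records$chain_b,
                    kd_molar = records$kd, pkd = records$pkd,
                    label = records$label, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a TPCP feature matrix as TSV
#'
#' The first column (`complex_id`) holds row ids; remaining column names
#' are property ids.
#'
#' @param path TSV file path.
#' @return `read_feature_matrix()`: numeric matrix with dimnames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "complex_id") {
    fail("feature matrix %s must have 'complex_id' as its first column", path)
  }
  x <- as.matrix(df[, -1, drop = FALSE])
  mode(x) <- "numeric"
  rownames(x) <- df$complex_id
  x
}

#' @rdname read_feature_matrix
#' @param x numeric matrix with row and column names.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(complex_id = rownames(x), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
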