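# TPCP encoding: from two-chain complexes to fixed-length feature vectors.

# Strip everything that is not a standard one-letter amino-acid code.
sanitize_sequence <- function(x) {
  gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", toupper(as.character(x)))
}

#' Sanitize complex records and filter short chains
#'
#' Removes nonstandard residue letters (X, B, Z, U, `*`, gaps, ...) from both
#' chains, then drops any complex whose sanitized chains are not both at
#' least `min_len` residues long. Chains of exactly `min_len` residues are
#' retained. Drop reasons are attached as the `"dropped"` attribute.
#'
#' @param records data.frame of complex records with columns `complex_id`,
#'   `chain_a`, `chain_b` and optionally `kd`, `pkd`, `label`.
#' @param min_len minimum sanitized chain length (default 50, the
#'   conventional cutoff below which a chain is treated as a peptide
#'   fragment rather than a protein domain).
#' @return the retained records, sanitized, with attribute `dropped` (a
#'   data.frame of `complex_id`, `reason`).
#' @export
sanitize_and_filter <- function(records, min_len = 50) {
  records <- validate_records(records)
  records$chain_a <- sanitize_sequence(records$chain_a)
  records$chain_b <- sanitize_sequence(records$chain_b)
  len_a <- nchar(records$chain_a)
  len_b <- nchar(records$chain_b)
  keep <- len_a >= min_len & len_b >= min_len
  dropped <- data.frame(
    complex_id = records$complex_id[!keep],
    reason = sprintf("chain shorter than %d residues after sanitization (A=%d, B=%d)",
                     min_len, len_a[!keep], len_b[!keep]),
    stringsAsFactors = FALSE
  )
  if (nrow(dropped) > 0) {
    message(sprintf("Dropped %d complex(es) with chains shorter than %d residues",
                    nrow(dropped), min_len))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

validate_records <- function(records) {
  if (!is.data.frame(records)) fail("records must be a data.frame")
  needed <- c("complex_id", "chain_a", "chain_b")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) {
    fail("records are missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (nrow(records) > 0) {
    ids <- as.character(records$complex_id)
    if (anyNA(ids) || any(!nzchar(ids))) {
      fail("every complex record must have a nonempty id")
    }
  }
  for (col in c("kd", "pkd", "label")) {
    if (!col %in% names(records)) records[[col]] <- rep(NA, nrow(records))
  }
  if (nrow(records) > 0 && any(!is.na(records$kd) & !is.na(records$label))) {
    i <- !is.na(records$kd) & !is.na(records$label)
    expect <- label_from_kd(records$kd[i])
    if (any(expect != as.character(records$label[i]))) {
      fail("record label disagrees with the Kd threshold for: %s",
           paste(records$complex_id[i][expect != records$label[i]],
                 collapse = ", "))
    }
  }
  records
}

#' Class label from a dissociation constant
#'
#' Complexes with Kd below 1e-8 M are labelled `"high"` (high binding
#' affinity); those with Kd at or above 1e-8 M are labelled `"low"`.
#'
#' @param kd dissociation constant(s) in molar; must be positive.
#' @return character vector of `"high"`/`"low"`.
#' @examples
#' label_from_kd(c(1e-9, 1e-8))  # "high" "low"
#' @export
label_from_kd <- function(kd) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0)) {
    fail("kd must be a positive, finite dissociation constant in molar")
  }
  ifelse(kd < 1e-8, "high", "low")
}

#' Amino-acid composition of a complex
#'
#' The fraction of each of the 20 standard amino acids over the
#' concatenation of both chains. Fractions sum to 1.
#'
#' @param chain_a,chain_b sanitized chain sequences (chain_b may be empty).
#' @return named numeric vector of 20 fractions, in AAindex residue order.
#' @export
aa_composition <- function(chain_a, chain_b = "") {
  s <- paste0(chain_a, chain_b)
  if (nchar(s) == 0) fail("cannot compute composition of an empty complex")
  letters <- strsplit(s, "")[[1]]
  if (!all(letters %in% AA20)) {
    fail("sequence contains nonstandard letters; sanitize first")
  }
  counts <- table(factor(letters, levels = AA20))
  out <- as.numeric(counts) / length(letters)
  names(out) <- AA20
  out
}

#' Total physicochemical property (TPCP) of a composition
#'
#' The composition-weighted sum `sum_i w(a_i) * PCP(a_i)` of one per-residue
#' property scale over a complex: the single fixed-length, order-independent
#' feature this package derives from each (complex, property) pair.
#'
#' @param comp composition vector from [aa_composition()].
#' @param table an [aaindex_table].
#' @return a single numeric TPCP value.
#' @export
tpcp <- function(comp, table) {
  stopifnot(inherits(table, "aaindex_table"))
  if (is.null(names(comp)) || !setequal(names(comp), AA20)) {
    fail("composition must be named with the 20 standard amino acids")
  }
  sum(comp[AA20] * table$values[AA20])
}

#' Encode complexes as a TPCP feature matrix
#'
#' @param records sanitized complex records (data.frame).
#' @param tables list of [aaindex_table] objects.
#' @return numeric matrix (complexes x properties); row names are complex
#'   ids, column names property ids. Rows follow record order and columns
#'   table order.
#' @export
encode_dataset <- function(records, tables) {
  records <- validate_records(records)
  if (nrow(records) == 0 || length(tables) == 0) {
    fail("need at least one record and one property table")
  }
  ids <- as.character(records$complex_id)
  if (anyDuplicated(ids)) {
    fail("duplicate complex ids: %s",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  prop_ids <- unname(vapply(tables, function(t) t$property_id, character(1)))
  if (anyDuplicated(prop_ids)) fail("duplicate property ids in tables")
  W <- t(vapply(seq_len(nrow(records)),
                function(i) aa_composition(records$chain_a[i], records$chain_b[i]),
                numeric(20)))
  P <- vapply(tables, function(t) t$values[AA20], numeric(20))
  X <- W %*% P
  dimnames(X) <- list(ids, prop_ids)
  X
}

#' Fit and apply [-1, 1] column scaling
#'
#' `fit_scaling()` learns, per column, the affine map sending the training
#' minimum to -1 and maximum to +1, applies it to the training matrix, and
#' stores the parameters in the `"scaling"` attribute. Constant training
#' columns map to 0. `apply_scaling()` applies stored parameters to another
#' matrix with the same columns, clipping values that fall outside the
#' training range to [-1, 1].
#'
#' @param x numeric feature matrix with column names.
#' @return `fit_scaling()`: the scaled matrix with attribute `scaling`
#'   (list of `min`, `max`, `ids`). `apply_scaling()`: the scaled matrix.
#' @export
fit_scaling <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) fail("x must be a numeric matrix")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  scaling <- list(min = mins, max = maxs, ids = colnames(x))
  out <- scale_with(x, scaling, clip = FALSE)
  attr(out, "scaling") <- scaling
  out
}

#' @rdname fit_scaling
#' @param scaling a scaling parameter list, or a matrix returned by
#'   [fit_scaling()] (its `"scaling"` attribute is used).
#' @export
apply_scaling <- function(x, scaling) {
  if (is.matrix(scaling)) scaling <- attr(scaling, "scaling")
  if (is.null(scaling)) fail("no scaling parameters supplied")
  if (!identical(colnames(x), scaling$ids)) {
    fail("column ids of the matrix do not match the fitted scaling")
  }
  scale_with(x, scaling, clip = TRUE)
}

scale_with <- function(x, scaling, clip) {
  rng <- scaling$max - scaling$min
  out <- x
  for (j in seq_len(ncol(x))) {
    if (rng[j] == 0) {
      out[, j] <- 0
    } else {
      out[, j] <- 2 * (x[, j] - scaling$min[j]) / rng[j] - 1
    }
  }
  if (clip) out <- pmin(pmax(out, -1), 1)
  out
}
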