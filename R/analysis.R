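# Feature-importance analyses and per-class compositional statistics.

#' Knock-out importance analysis
#'
#' For each selected property, the classifier is re-evaluated by the same
#' stratified cross-validation with that single property removed; the drop
#' in accuracy (baseline minus reduced) measures the property's individual
#' contribution. The same fold seed is used for every evaluation, so
#' differences are attributable to the knocked-out column alone and the
#' result is invariant to the order in which properties are examined.
#'
#' @param x feature matrix containing at least the selected columns.
#' @param labels class labels per row.
#' @param selected character vector of property ids (m >= 2).
#' @param cost,gamma SVM parameters.
#' @param folds,seed cross-validation protocol.
#' @return data.frame of class `knockout_report` with columns
#'   `property_id`, `difference_accuracy` (percentage points) and
#'   `baseline_accuracy`.
#' @export
knockout_analysis <- function(x, labels, selected = colnames(x),
                              cost = 1, gamma = 1 / length(selected),
                              folds = 10, seed = 1L) {
  selected <- check_selected(x, selected)
  if (length(selected) < 2) {
    fail("knock-out analysis needs at least 2 selected properties")
  }
  baseline <- cross_validate(x[, selected, drop = FALSE], labels, k = folds,
                             cost = cost, gamma = gamma, seed = seed)$accuracy
  diffs <- vapply(selected, function(p) {
    rest <- setdiff(selected, p)
    acc <- cross_validate(x[, rest, drop = FALSE], labels, k = folds,
                          cost = cost, gamma = gamma, seed = seed)$accuracy
    baseline - acc
  }, numeric(1))
  out <- data.frame(property_id = selected,
                    difference_accuracy = unname(diffs),
                    baseline_accuracy = baseline,
                    stringsAsFactors = FALSE)
  class(out) <- c("knockout_report", "data.frame")
  out
}

#' Main-effect-difference (MED) feature ranking
#'
#' Ranks the selected properties by an orthogonal-design contribution
#' score. A two-level orthogonal array with at least `m` factor columns is
#' built; each row keeps the properties whose assigned column is at
#' level 1 and drops the rest (rows that would drop everything are
#' skipped). Every row's feature subset is scored by stratified
#' cross-validation accuracy, and the MED of a property is the mean
#' accuracy of rows keeping it minus the mean accuracy of rows dropping
#' it. Larger MED means a greater contribution to prediction performance.
#'
#' @inheritParams knockout_analysis
#' @param factor_assignment optional integer vector assigning each
#'   selected property to a distinct orthogonal-array column (defaults to
#'   columns 1..m); useful for checking stability of the ranking under
#'   re-assignment.
#' @return data.frame of class `med_report` with columns `rank`,
#'   `property_id`, `med` (percentage points), ordered by rank. Ranks are
#'   a permutation of 1..m, descending in MED.
#' @export
main_effect_difference <- function(x, labels, selected = colnames(x),
                                   cost = 1, gamma = 1 / length(selected),
                                   folds = 10, seed = 1L,
                                   factor_assignment = NULL) {
  selected <- check_selected(x, selected)
  m <- length(selected)
  if (m < 2) fail("MED analysis needs at least 2 selected properties")
  if (m > 31) {
    fail("MED analysis supports at most 31 properties (largest packaged orthogonal array)")
  }
  oa_full <- oa_two_level(m)
  n_cols <- 2L^ceiling(log2(m + 1)) - 1L
  if (is.null(factor_assignment)) factor_assignment <- seq_len(m)
  if (length(factor_assignment) != m ||
      anyDuplicated(factor_assignment) ||
      any(factor_assignment < 1) || any(factor_assignment > n_cols)) {
    fail("factor_assignment must map the %d properties to distinct array columns in 1..%d",
         m, n_cols)
  }
  oa <- oa_two_level(n_cols)[, factor_assignment, drop = FALSE]
  keep_rows <- rowSums(oa == 1L) > 0
  oa <- oa[keep_rows, , drop = FALSE]
  acc <- vapply(seq_len(nrow(oa)), function(i) {
    subset <- selected[oa[i, ] == 1L]
    cross_validate(x[, subset, drop = FALSE], labels, k = folds,
                   cost = cost, gamma = gamma, seed = seed)$accuracy
  }, numeric(1))
  med <- vapply(seq_len(m), function(j) {
    mean(acc[oa[, j] == 1L]) - mean(acc[oa[, j] == 2L])
  }, numeric(1))
  out <- data.frame(rank = rank(-med, ties.method = "first"),
                    property_id = selected, med = med,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("med_report", "data.frame")
  out
}

check_selected <- function(x, selected) {
  selected <- as.character(selected)
  miss <- setdiff(selected, colnames(x))
  if (length(miss) > 0) {
    fail("unknown property id(s): %s (known: %s%s)",
         paste(miss, collapse = ", "),
         paste(head(colnames(x), 5), collapse = ", "),
         if (ncol(x) > 5) ", ..." else "")
  }
  selected
}

#' Per-class amino-acid composition comparison
#'
#' Mean composition percentage of each amino acid over the complexes of
#' the high and of the low binding-affinity class, and their difference
#' (high minus low, percentage points). Because each complex's
#' composition sums to 100%, the differences sum to zero.
#'
#' @param records labeled complex records (both classes present).
#' @return data.frame with columns `amino_acid` (three-letter), `aa`
#'   (one-letter), `high_pct`, `low_pct`, `difference`.
#' @export
composition_comparison <- function(records) {
  records <- validate_records(records)
  lab <- as.character(records$label)
  if (anyNA(lab)) fail("all records must be labeled")
  for (cl in c("high", "low")) {
    if (sum(lab == cl) == 0) fail("class '%s' has no records", cl)
  }
  W <- 100 * t(vapply(seq_len(nrow(records)),
                      function(i) aa_composition(records$chain_a[i],
                                                 records$chain_b[i]),
                      numeric(20)))
  high <- colMeans(W[lab == "high", , drop = FALSE])
  low <- colMeans(W[lab == "low", , drop = FALSE])
  data.frame(amino_acid = AA20_NAMES, aa = AA20,
             high_pct = unname(high), low_pct = unname(low),
             difference = unname(high - low),
             stringsAsFactors = FALSE)
}

#' Per-class mean of a physicochemical property
#'
#' Scores each complex by a per-residue property scale, optionally
#' restricted to a subset of amino acids (e.g. the hydrophobic residues),
#' and averages the per-complex scores within each class. With
#' `weighting = "sum"` the complex score is the sum of the property value
#' over the (restricted) residues; with `weighting = "mean"` it is their
#' mean, i.e. the composition-weighted property value.
#'
#' @param records labeled complex records (both classes present).
#' @param table an [aaindex_table].
#' @param restrict optional character vector of one-letter codes to which
#'   the residues are restricted; every complex must retain at least one
#'   residue.
#' @param weighting `"sum"` or `"mean"` (see above).
#' @return named numeric vector `c(high = ..., low = ...)`.
#' @export
class_property_mean <- function(records, table, restrict = NULL,
                                weighting = c("sum", "mean")) {
  weighting <- match.arg(weighting)
  records <- validate_records(records)
  stopifnot(inherits(table, "aaindex_table"))
  lab <- as.character(records$label)
  if (anyNA(lab)) fail("all records must be labeled")
  if (!is.null(restrict)) {
    restrict <- intersect(AA20, restrict)
    if (length(restrict) == 0) {
      fail("restriction leaves no standard amino acids")
    }
  } else {
    restrict <- AA20
  }
  score <- vapply(seq_len(nrow(records)), function(i) {
    letters <- strsplit(paste0(records$chain_a[i], records$chain_b[i]),
                        "")[[1]]
    letters <- letters[letters %in% restrict]
    if (length(letters) == 0) {
      fail("complex '%s' has no residues in the restriction",
           records$complex_id[i])
    }
    v <- table$values[letters]
    if (weighting == "sum") sum(v) else mean(v)
  }, numeric(1))
  c(high = mean(score[lab == "high"]), low = mean(score[lab == "low"]))
}
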