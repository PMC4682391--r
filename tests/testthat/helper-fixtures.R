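# Shared fixture builders: everything is generated in code at test time.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa_table <- function(id = "RND0000001") {
  aaindex_table(id, stats::setNames(stats::rnorm(20), AA), "random test scale")
}

random_sequence <- function(len, prob = NULL) {
  paste(sample(AA, len, replace = TRUE, prob = prob), collapse = "")
}

toy_records <- function(n = 4, len = 60, seed = 42) {
  seqaffinity:::with_seed(seed, data.frame(
    complex_id = sprintf("CPX%02d", seq_len(n)),
    chain_a = vapply(seq_len(n), function(i) random_sequence(len), ""),
    chain_b = vapply(seq_len(n), function(i) random_sequence(len), ""),
    stringsAsFactors = FALSE
  ))
}

# Two well-separated classes on every feature: linearly separable.
separable_data <- function(n = 60, d = 3, gap = 6, seed = 1) {
  seqaffinity:::with_seed(seed, {
    labels <- rep(c("high", "low"), length.out = n)
    x <- matrix(stats::rnorm(n * d), n, d)
    x[labels == "high", ] <- x[labels == "high", ] + gap
    colnames(x) <- sprintf("F%02d", seq_len(d))
    rownames(x) <- sprintf("S%03d", seq_len(n))
    list(x = x, labels = labels)
  })
}

# AAindex1 text for a single entry, assembled in code.
aaindex_entry_text <- function(id, values, description = "test entry") {
  v <- formatC(values, digits = 17, format = "g")
  c(paste("H", id),
    paste("D", description),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste(" ", paste(v[1:10], collapse = "  ")),
    paste(" ", paste(v[11:20], collapse = "  ")),
    "//")
}
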