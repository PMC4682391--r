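# Amino-acid property tables: AAindex1 flat-file IO and packaged scales.

#' Construct an amino-acid property table
#'
#' A property table holds one numerical index over the 20 standard amino
#' acids, e.g. a hydrophobicity scale or a secondary-structure propensity.
#' Such tables supply the per-residue values `PCP(a)` that the TPCP encoding
#' averages over a complex (see [tpcp()]).
#'
#' @param property_id short accession string (e.g. `"CHOP780101"`).
#' @param values named numeric vector with exactly one finite value for each
#'   of the 20 standard one-letter amino-acid codes.
#' @param description free-text description of the scale.
#' @return an object of class `aaindex_table`.
#' @examples
#' tab <- aaindex_table("TOY000001", setNames(1:20, seqaffinity:::AA20))
#' tab$values[["A"]]
#' @export
aaindex_table <- function(property_id, values, description = "") {
  if (!is.character(property_id) || length(property_id) != 1 ||
      is.na(property_id) || !nzchar(property_id)) {
    fail("property_id must be a nonempty string")
  }
  if (is.null(names(values)) || !setequal(names(values), AA20) ||
      length(values) != 20) {
    fail("values must be named with exactly the 20 standard amino acids")
  }
  values <- as.numeric(values[AA20])
  names(values) <- AA20
  if (any(!is.finite(values))) {
    fail("property table '%s' has missing or non-finite values", property_id)
  }
  structure(
    list(property_id = property_id, description = description,
         values = values),
    class = "aaindex_table"
  )
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat(sprintf("<aaindex_table> %s: %s\n", x$property_id, x$description))
  print(round(x$values, 4))
  invisible(x)
}

#' Read property tables from an AAindex1 flat file
#'
#' Parses the AAindex1 dialect: entries terminated by `//`, with an `H` line
#' carrying the accession, `D` line(s) the description, and an `I` block
#' whose two rows of ten numbers list the values in the order
#' A R N D C Q E G H I / L K M F P S T W Y V. Entries with any `NA` value
#' are skipped (the TPCP encoding needs a value per amino acid) and their
#' accessions are reported via a message and the `"skipped"` attribute.
#'
#' @param path path to a file (or connection) in AAindex1 format.
#' @return list of [aaindex_table] objects in file order, named by accession,
#'   with attribute `skipped` holding accessions of entries dropped for
#'   missing values.
#' @seealso [write_aaindex()], [builtin_property_tables()]
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | TRUE]  # keep structure, tolerate blanks
  ends <- grep("^//", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0 && any(nzchar(trimws(lines)))) {
    fail("malformed AAindex stream: no '//' entry terminator found")
  }
  tables <- list()
  skipped <- character(0)
  for (e in seq_along(ends)) {
    entry <- lines[starts[e]:(ends[e] - 1L)]
    if (all(!nzchar(trimws(entry)))) next
    h_line <- grep("^H\\s", entry)
    i_line <- grep("^I\\s", entry)
    accession <- if (length(h_line) > 0) {
      trimws(sub("^H\\s+", "", entry[h_line[1]]))
    } else {
      sprintf("<entry %d>", e)
    }
    if (length(h_line) == 0) {
      fail("malformed AAindex entry %s: missing H (accession) line", accession)
    }
    if (length(i_line) == 0) {
      fail("malformed AAindex entry %s: missing I (index data) block", accession)
    }
    d_line <- grep("^D\\s", entry)
    description <- if (length(d_line) > 0) {
      desc <- sub("^D\\s+", "", entry[d_line[1]])
      j <- d_line[1] + 1L
      while (j <= length(entry) && grepl("^\\s+\\S", entry[j])) {
        desc <- paste(desc, trimws(entry[j]))
        j <- j + 1L
      }
      desc
    } else {
      ""
    }
    value_lines <- entry[seq(i_line[1] + 1L, length(entry))]
    tokens <- unlist(strsplit(trimws(paste(value_lines, collapse = " ")),
                              "\\s+"))
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) < 20) {
      fail("malformed AAindex entry %s: expected 20 values, found %d",
           accession, length(tokens))
    }
    tokens <- tokens[seq_len(20)]
    vals <- suppressWarnings(as.numeric(ifelse(tokens == "NA", NA, tokens)))
    if (any(is.na(vals) & tokens != "NA")) {
      fail("malformed AAindex entry %s: non-numeric value '%s'",
           accession, tokens[which(is.na(vals) & tokens != "NA")[1]])
    }
    if (anyNA(vals)) {
      skipped <- c(skipped, accession)
      next
    }
    names(vals) <- AA20
    tables[[accession]] <- aaindex_table(accession, vals, description)
  }
  if (length(skipped) > 0) {
    message(sprintf("Skipped %d AAindex entr%s with missing values: %s",
                    length(skipped), if (length(skipped) == 1) "y" else "ies",
                    paste(skipped, collapse = ", ")))
  }
  attr(tables, "skipped") <- skipped
  tables
}

#' Write property tables in AAindex1 format
#'
#' Values are written with 17 significant digits so that reading the file
#' back yields bit-identical doubles.
#'
#' @param tables list of [aaindex_table] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(tables, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tab in tables) {
    stopifnot(inherits(tab, "aaindex_table"))
    v <- formatC(tab$values, digits = 17, format = "g")
    writeLines(c(
      paste("H", tab$property_id),
      paste("D", tab$description),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste(" ", paste(v[1:10], collapse = "  ")),
      paste(" ", paste(v[11:20], collapse = "  ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' Packaged physicochemical property tables
#'
#' Returns the three per-residue scales shipped with the package:
#' `GUYH850105` (apparent partition energies from the Chothia
#' buried-molar-fraction index, a buried-hydrophobicity scale),
#' `SNEP660104` (Sneath's principal component IV, associated with
#' hydroxythiolation and hydrogen-bonding capacity) and `CHOP780101`
#' (Chou--Fasman normalized beta-turn frequency). These are the three
#' scales most informative for discriminating high- from low-affinity
#' heterodimers in the 216-complex benchmark this package models.
#'
#' @return named list of three [aaindex_table] objects.
#' @examples
#' builtin_property_tables()[["CHOP780101"]]$values[["A"]]  # 0.66
#' @export
builtin_property_tables <- function() {
  path <- system.file("extdata", "builtin_properties.aaindex",
                      package = "seqaffinity")
  suppressMessages(read_aaindex(path))
}

#' Reference per-class amino-acid composition
#'
#' Mean amino-acid composition percentages of the high (HBA) and low (LBA)
#' binding-affinity classes of a published 216-complex heterodimer
#' benchmark (108 complexes per class, classes split at Kd = 1e-8 M).
#' Shipped as a plain-text fixture; used for compositional comparisons when
#' the underlying sequences are not at hand.
#'
#' @return data.frame with columns `amino_acid` (three-letter code),
#'   `aa` (one-letter code), `high_pct`, `low_pct`.
#' @export
reference_class_composition <- function() {
  path <- system.file("extdata", "hetero216_aac.tsv", package = "seqaffinity")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
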