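# Thin wrapper around the Open Babel command-line tool. Bulk conversion
# through the CLI is orders of magnitude faster than per-molecule bindings,
# which matters for libraries of 10^4-10^6 enumerated products.

.obabel <- function() {
  p <- Sys.which("obabel")
  .check(nzchar(p),
         "Open Babel ('obabel') was not found on the PATH; it is required for SMILES parsing, canonicalization and descriptor calculation.")
  unname(p)
}

.run_obabel <- function(args) {
  out <- suppressWarnings(system2(.obabel(), args,
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  .check(is.null(status) || status == 0L, "obabel failed (exit %s)", status)
  out
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical SMILES in a single batch call.
#' Entries that fail to parse are returned as `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, seq_len(n)), fin)
  suppressWarnings(system2(.obabel(),
                           c(shQuote(fin), "-osmi", "-O", shQuote(fout), "-xc"),
                           stdout = FALSE, stderr = FALSE))
  res <- rep(NA_character_, n)
  if (file.exists(fout)) {
    out <- readLines(fout, warn = FALSE)
    out <- out[nzchar(out)]
    if (length(out)) {
      parts <- strsplit(out, "[ \t]+")
      can <- vapply(parts, `[[`, character(1), 1L)
      idx <- suppressWarnings(
        as.integer(vapply(parts, function(p) p[length(p)], character(1))))
      ok <- !is.na(idx) & idx >= 1L & idx <= n
      res[idx[ok]] <- can[ok]
    }
  }
  res
}

# Descriptors appended by obabel in one pass; all numeric except formula,
# which is parsed separately into element counts.
.OB_NUMERIC <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
                 "rotors", "atoms", "bonds", "sbonds", "dbonds", "tbonds",
                 "abonds")

# Returns a data.frame with one row per input SMILES (NA rows on parse
# failure): canonical smiles, the numeric obabel descriptors and the formula.
.obabel_descriptors <- function(smiles) {
  n <- length(smiles)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, seq_len(n)), fin)
  suppressWarnings(system2(.obabel(),
                           c(shQuote(fin), "-osmi", "-O", shQuote(fout), "-xc",
                             "--append", shQuote(paste(c(.OB_NUMERIC, "formula"),
                                                       collapse = " "))),
                           stdout = FALSE, stderr = FALSE))
  vals <- matrix(NA_real_, n, length(.OB_NUMERIC),
                 dimnames = list(NULL, .OB_NUMERIC))
  res <- data.frame(cansmi = rep(NA_character_, n), vals,
                    formula = NA_character_, stringsAsFactors = FALSE)
  if (!file.exists(fout)) return(res)
  out <- readLines(fout, warn = FALSE)
  out <- out[nzchar(out)]
  for (line in out) {
    p <- strsplit(line, "[ \t]+")[[1]]
    # layout: cansmi id <numeric...> formula
    if (length(p) != length(.OB_NUMERIC) + 3L) next
    i <- suppressWarnings(as.integer(p[2]))
    if (is.na(i) || i < 1L || i > n) next
    res$cansmi[i] <- p[1]
    res[i, .OB_NUMERIC] <- suppressWarnings(as.numeric(p[3:(2 + length(.OB_NUMERIC))]))
    res$formula[i] <- p[length(p)]
  }
  res
}

# Element counts from a molecular formula string such as "C7H8N2O".
.parse_formula <- function(formula, elements = c("C", "H", "N", "O", "S", "P",
                                                 "F", "Cl", "Br", "I")) {
  out <- matrix(0, length(formula), length(elements),
                dimnames = list(NULL, paste0("n", elements)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  toks <- regmatches(formula, m)
  for (i in seq_along(formula)) {
    if (is.na(formula[i])) { out[i, ] <- NA_real_; next }
    for (t in toks[[i]]) {
      el <- sub("[0-9]+$", "", t)
      ct <- sub("^[A-Za-z]+", "", t)
      ct <- if (nzchar(ct)) as.numeric(ct) else 1
      j <- match(el, elements)
      if (!is.na(j)) out[i, j] <- out[i, j] + ct
    }
  }
  out
}
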