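#' Truncate ICD9-CM diagnosis codes to their 3-character stem
#'
#' ICD9-CM codes carry three to five alphanumeric characters with an optional
#' decimal point after the third; the detail after the decimal point is
#' discarded so that, e.g., `"250.01"` and `"250.70"` both map to the Diabetes
#' Mellitus stem `"250"`. Matching is case-insensitive (codes are uppercased).
#'
#' @param code character vector of raw ICD9-CM codes.
#' @return character vector of truncated codes, same length as `code`.
#' @examples
#' truncate_icd9(c("250.01", "V27", "648.8"))
#' @export
truncate_icd9 <- function(code) {
  stopifnot(is.character(code), length(code) >= 1)
  code <- toupper(trimws(code))
  stem <- sub("\\..*$", "", code)
  bad <- !grepl("^[0-9A-Z]{3,5}$", stem) | nchar(stem) < 3
  if (any(bad)) {
    stop("malformed ICD9-CM code(s): ", paste(sQuote(code[bad]), collapse = ", "))
  }
  stem
}

#' Truncate ATC drug codes to the first four levels (5 characters)
#'
#' ATC codes have seven characters over five levels; the fifth level (chemical
#' substance, last two characters) is discarded, keeping the first five
#' characters, e.g. `"A10BA02"` (metformin) truncates to the biguanides class
#' `"A10BA"`. Codes already at or below five characters pass through unchanged.
#'
#' @param code character vector of raw ATC codes.
#' @return character vector of truncated codes.
#' @examples
#' truncate_atc(c("A10BA02", "C09AA05", "N02BE"))
#' @export
truncate_atc <- function(code) {
  stopifnot(is.character(code), length(code) >= 1)
  code <- toupper(trimws(code))
  bad <- !grepl("^[0-9A-Z]{1,7}$", code)
  if (any(bad)) {
    stop("malformed ATC code(s): ", paste(sQuote(code[bad]), collapse = ", "))
  }
  substr(code, 1L, pmin(5L, nchar(code)))
}

#' Construct a code vocabulary
#'
#' A vocabulary fixes the feature layout of every patient vector: all
#' (truncated) diagnosis codes first, then all drug codes, each family sorted
#' lexicographically. The total length `D` is the dimensionality of the binary
#' feature space.
#'
#' @param diagnosis_codes character vector of (raw or truncated) ICD9-CM codes.
#' @param drug_codes character vector of (raw or truncated) ATC codes.
#' @return an object of class `code_vocabulary` with elements
#'   `diagnosis_codes`, `drug_codes`, `codes` (the concatenated feature order)
#'   and `D`.
#' @export
code_vocabulary <- function(diagnosis_codes, drug_codes) {
  dx <- sort(unique(truncate_icd9(diagnosis_codes)))
  rx <- sort(unique(truncate_atc(drug_codes)))
  overlap <- intersect(dx, rx)
  if (length(overlap) > 0) {
    stop("codes present in both families: ", paste(overlap, collapse = ", "))
  }
  structure(
    list(diagnosis_codes = dx, drug_codes = rx,
         codes = c(dx, rx), D = length(dx) + length(rx)),
    class = "code_vocabulary"
  )
}

#' @export
print.code_vocabulary <- function(x, ...) {
  cat("Code vocabulary: D =", x$D, "features (",
      length(x$diagnosis_codes), "diagnosis +",
      length(x$drug_codes), "drug codes )\n")
  invisible(x)
}

#' Family (diagnosis/drug) of each vocabulary position
#' @param vocab a [code_vocabulary()].
#' @return character vector of length `D` with values `"diagnosis"`/`"drug"`.
#' @export
vocab_family <- function(vocab) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  rep(c("diagnosis", "drug"),
      c(length(vocab$diagnosis_codes), length(vocab$drug_codes)))
}

# Signature codes that the default study populations load on: lead chronic
# codes, comorbidity/secondary codes per sub-phenotype, and common acute
# background codes.
signature_codes <- function() {
  list(
    diagnosis = c(
      # lead chronic / pregnancy codes
      "250", "272", "401", "V27", "648", "650", "664",
      # comorbidity & complication codes
      "427", "414", "440", "278", "715", "530", "300", "366", "362", "443", "403",
      "585", "357", "251", "337", "V58", "276", "564", "787",
      "V22", "644", "646", "661", "663",
      # common acute / unspecific codes
      "465", "526", "780", "719", "724", "790",
      "079", "462", "466", "490", "558", "599", "682", "729"),
    drug = c(
      "A10BA", "A10AB", "A10AE", "A10AC", "A10AD", "A10BB",
      "C09AA", "C10AA", "C03AA", "C07AB", "C08CA",
      "B01AC", "A02BC", "H04AA", "V04CA", "A10BD", "C09BA", "C10BA",
      "B03AA", "B03BB", "H03CA", "A12AA", "G02AB",
      "M01AE", "N02BB", "N02BE", "N05BA")
  )
}

#' Default study vocabulary
#'
#' Builds a vocabulary with the study's dimensionality — 1,517 diagnosis and
#' 746 drug positions (2,263 features) by default — consisting of the clinical
#' signature codes the default cohort generator uses (e.g. `"250"`, `"401"`,
#' `"A10BA"`, `"C09AA"`) embedded in deterministic placeholder codes that fill
#' the remaining positions. Smaller sizes are convenient for examples/tests.
#'
#' @param n_diagnosis number of diagnosis positions (>= number of signature
#'   diagnosis codes).
#' @param n_drug number of drug positions (>= number of signature drug codes).
#' @return a [code_vocabulary()].
#' @export
default_vocabulary <- function(n_diagnosis = 1517, n_drug = 746) {
  sig <- signature_codes()
  stopifnot(n_diagnosis >= length(sig$diagnosis), n_drug >= length(sig$drug))

  dx_pool <- c(sprintf("%03d", 0:999), sprintf("V%02d", 0:99),
               sprintf("E%03d", 0:999))
  dx_pad <- setdiff(dx_pool, sig$diagnosis)
  dx <- c(sig$diagnosis, dx_pad[seq_len(n_diagnosis - length(sig$diagnosis))])

  grid <- expand.grid(l5 = LETTERS[1:4], l4 = LETTERS[1:6],
                      l23 = sprintf("%02d", 1:16),
                      l1 = c("A", "B", "C", "D", "G", "H", "J", "L",
                             "M", "N", "P", "R", "S", "V"),
                      stringsAsFactors = FALSE)
  rx_pool <- sort(paste0(grid$l1, grid$l23, grid$l4, grid$l5))
  rx_pad <- setdiff(rx_pool, sig$drug)
  rx <- c(sig$drug, rx_pad[seq_len(n_drug - length(sig$drug))])

  code_vocabulary(dx, rx)
}

#' Bundle a patient's raw codes
#'
#' @param patient_id opaque identifier.
#' @param diagnosis character vector of raw ICD9-CM codes (may be empty).
#' @param drug character vector of raw ATC codes (may be empty).
#' @return an object of class `patient_code_set`.
#' @export
patient_code_set <- function(patient_id, diagnosis = character(),
                             drug = character()) {
  structure(list(patient_id = as.character(patient_id),
                 diagnosis = as.character(diagnosis),
                 drug = as.character(drug)),
            class = "patient_code_set")
}

#' Assemble the binary patient-by-code feature matrix
#'
#' Entry (i, j) is 1 iff patient i carries vocabulary code j at least once;
#' duplicate raw codes mapping to the same truncated code collapse to a single
#' presence bit. Codes absent from the vocabulary are either dropped with a
#' reported count (default) or rejected.
#'
#' @param patients list of [patient_code_set()] objects.
#' @param vocab a [code_vocabulary()].
#' @param unknown policy for codes outside the vocabulary: `"drop"` (default,
#'   count reported via the `"n_dropped"` attribute and a message) or
#'   `"error"`.
#' @return integer matrix (patients x `D`) with 0/1 entries; rownames are
#'   patient ids, colnames the vocabulary codes.
#' @export
build_feature_matrix <- function(patients, vocab, unknown = c("drop", "error")) {
  stopifnot(inherits(vocab, "code_vocabulary"), is.list(patients))
  unknown <- match.arg(unknown)
  n <- length(patients)
  X <- matrix(0L, nrow = n, ncol = vocab$D,
              dimnames = list(vapply(patients, `[[`, "", "patient_id"),
                              vocab$codes))
  dropped <- 0L
  for (i in seq_len(n)) {
    p <- patients[[i]]
    stopifnot(inherits(p, "patient_code_set"))
    codes <- character()
    if (length(p$diagnosis)) codes <- truncate_icd9(p$diagnosis)
    if (length(p$drug)) codes <- c(codes, truncate_atc(p$drug))
    codes <- unique(codes)
    j <- match(codes, vocab$codes)
    if (anyNA(j)) {
      if (unknown == "error") {
        stop("patient ", p$patient_id, " carries codes outside the vocabulary: ",
             paste(codes[is.na(j)], collapse = ", "))
      }
      dropped <- dropped + sum(is.na(j))
      j <- j[!is.na(j)]
    }
    X[i, j] <- 1L
  }
  if (dropped > 0) {
    message("build_feature_matrix: dropped ", dropped,
            " code occurrence(s) outside the vocabulary")
  }
  attr(X, "n_dropped") <- dropped
  X
}

#' Read a vocabulary from a plain-text file
#'
#' Format: one code per line, with section headers `#DX` and `#ATC` switching
#' between the diagnosis and drug families.
#'
#' @param path file path.
#' @return a [code_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  fam <- NA_character_
  dx <- character(); rx <- character()
  for (ln in lines) {
    if (ln == "#DX") { fam <- "dx"; next }
    if (ln == "#ATC") { fam <- "atc"; next }
    if (is.na(fam)) stop("code line before any #DX/#ATC header: ", ln)
    if (fam == "dx") dx <- c(dx, ln) else rx <- c(rx, ln)
  }
  code_vocabulary(dx, rx)
}

#' Write a vocabulary to a plain-text file
#' @param vocab a [code_vocabulary()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  writeLines(c("#DX", vocab$diagnosis_codes, "#ATC", vocab$drug_codes), path)
  invisible(path)
}
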