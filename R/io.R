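#' Load a user-supplied patient table as a cohort
#'
#' Expected CSV layout: columns `patient_id`, `age`, `sex`, `crg`,
#' `dx_codes`, `atc_codes`, the last two holding semicolon-separated raw
#' ICD9-CM / ATC codes (empty allowed). Codes are truncated through the code
#' module and assembled against the given vocabulary; codes outside the
#' vocabulary are dropped with a reported count.
#'
#' @param path CSV file path.
#' @param vocab a [code_vocabulary()], or a path to a vocabulary file in the
#'   [read_vocabulary()] format.
#' @return a `cohort` (with `subgroup` set to the CRG label).
#' @export
load_user_cohort <- function(path, vocab) {
  if (is.character(vocab)) vocab <- read_vocabulary(vocab)
  stopifnot(inherits(vocab, "code_vocabulary"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "age", "sex", "crg", "dx_codes", "atc_codes")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("patient CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(tab$age))
  bad <- which(is.na(age) | age < 0)
  if (length(bad)) stop("malformed age in row(s): ", paste(bad, collapse = ", "))
  split_codes <- function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)
    lapply(parts, function(p) trimws(p[nzchar(trimws(p))]))
  }
  dx <- split_codes(tab$dx_codes)
  rx <- split_codes(tab$atc_codes)
  patients <- lapply(seq_len(nrow(tab)), function(i) {
    patient_code_set(tab$patient_id[i], diagnosis = dx[[i]], drug = rx[[i]])
  })
  X <- build_feature_matrix(patients, vocab, unknown = "drop")
  if (all(X == 0L) && nrow(X) > 0) {
    warning("no patient code matched the vocabulary: all-zero matrix")
  }
  message("loaded ", nrow(X), " patients x ", ncol(X), " features (",
          attr(X, "n_dropped"), " code occurrence(s) dropped)")
  structure(list(X = X, crg = tab$crg, subgroup = tab$crg, age = age,
                 sex = tab$sex, patient_id = tab$patient_id, vocab = vocab,
                 n = nrow(X)),
            class = "cohort")
}

#' Write a cohort as a patient CSV in the documented layout
#'
#' Inverse of [load_user_cohort()]: one row per patient with the carried
#' (truncated) codes re-joined by semicolons.
#'
#' @param cohort a `cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  fam <- vocab_family(cohort$vocab)
  join <- function(i, which_fam) {
    codes <- cohort$vocab$codes[fam == which_fam & cohort$X[i, ] == 1L]
    paste(codes, collapse = ";")
  }
  tab <- data.frame(
    patient_id = cohort$patient_id,
    age = cohort$age,
    sex = cohort$sex,
    crg = cohort$crg,
    dx_codes = vapply(seq_len(cohort$n), join, "", "diagnosis"),
    atc_codes = vapply(seq_len(cohort$n), join, "", "drug"))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
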