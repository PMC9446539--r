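#' Specify one CRG population for the cohort generator
#'
#' A group spec names a clinical risk group (CRG), its size and demographics,
#' and one or more latent sub-phenotypes. Each sub-phenotype carries its own
#' per-code Bernoulli presence-rate vector over the vocabulary, a mixing
#' weight, and optional demographic overrides; a patient first draws a
#' sub-phenotype by weight, then each code bit independently.
#'
#' @param crg_label CRG name, e.g. `"CRG-5424"`.
#' @param n_patients group size (>= 1).
#' @param phenotypes named list; each element is a list with `weight`
#'   (positive, normalized internally), `rates` (numeric length-`D` vector in
#'   \[0,1\]), and optionally `age_mean`, `age_sd`, `sex_ratio` overriding the
#'   group-level values, plus `severity_range` (length-2 numeric) and
#'   `graded_codes` (character): when present, each patient draws a severity
#'   factor uniformly from the range and the rates of the graded codes are
#'   scaled by it (normalized by the range mean, so the group-level presence
#'   rates are preserved while mildly affected patients carry sparser code
#'   bundles).
#' @param age_mean,age_sd group age distribution (normal, truncated at 0), years.
#' @param sex_ratio fraction female in \[0,1\].
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(crg_label, n_patients, phenotypes,
                       age_mean, age_sd, sex_ratio = 0.5) {
  stopifnot(is.character(crg_label), n_patients >= 1,
            is.list(phenotypes), length(phenotypes) >= 1,
            !is.null(names(phenotypes)), all(nzchar(names(phenotypes))),
            age_sd > 0, sex_ratio >= 0, sex_ratio <= 1)
  for (ph in phenotypes) {
    stopifnot(is.numeric(ph$rates), all(ph$rates >= 0), all(ph$rates <= 1),
              is.numeric(ph$weight), ph$weight > 0)
  }
  structure(list(crg_label = crg_label, n_patients = as.integer(n_patients),
                 phenotypes = phenotypes, age_mean = age_mean,
                 age_sd = age_sd, sex_ratio = sex_ratio),
            class = "group_spec")
}

# Build a rate vector: low background everywhere, elevated named codes.
make_rates <- function(vocab, elevated, background = 0.01) {
  r <- rep(background, vocab$D)
  names(r) <- vocab$codes
  if (length(elevated)) {
    j <- match(names(elevated), vocab$codes)
    if (anyNA(j)) {
      stop("signature code(s) missing from vocabulary: ",
           paste(names(elevated)[is.na(j)], collapse = ", "))
    }
    r[j] <- unlist(elevated)
  }
  r
}

#' Default study group specifications
#'
#' Emulates the study populations: CRG-1000 (46,835 healthy patients),
#' CRG-5192 (12,447 hypertensives), CRG-5424 (2,166 diabetics, a mixture of
#' biguanide-treated and insulin-dependent sub-phenotypes), and — in case
#' study 2 — CRG-6144 (3,179 multimorbid patients with co-occurring diabetes
#' and hypertension). A small pregnancy/delivery sub-phenotype spans CRG-5192
#' (pregnancy-induced hypertension) and CRG-1000, forming one additional
#' latent group. Case 1 therefore carries five latent sub-groups and case 2
#' six. Each sub-phenotype elevates its clinical signature codes (lead
#' diagnosis 0.85, lead drugs 0.6–0.85, secondary codes 0.3–0.55) over a low
#' background rate scaled by morbidity.
#'
#' @param case `1` (CRGs 1000/5192/5424) or `2` (adds CRG-6144).
#' @param vocab a [code_vocabulary()] containing the signature codes (see
#'   [default_vocabulary()]).
#' @param background background presence rate for non-signature codes.
#' @return list of [group_spec()] objects.
#' @export
default_study_specs <- function(case = 1, vocab = default_vocabulary(),
                                background = 0.002) {
  stopifnot(case %in% c(1, 2), inherits(vocab, "code_vocabulary"))

  # Shared acute/unspecific codes every sub-phenotype carries at low rates.
  shared <- list("465" = 0.10, "526" = 0.08, "780" = 0.08, "719" = 0.05,
                 "724" = 0.06, "790" = 0.06,
                 "N02BE" = 0.30, "M01AE" = 0.25, "N05BA" = 0.08)
  with_shared <- function(extra) utils::modifyList(shared, extra)

  # Healthy patients: only mild acute codes, everything below 0.15.
  healthy_codes <- with_shared(list(
    "465" = 0.12, "780" = 0.10, "526" = 0.09,
    "079" = 0.06, "462" = 0.08, "466" = 0.08, "490" = 0.06, "558" = 0.05,
    "599" = 0.06, "682" = 0.04, "729" = 0.05))
  # Delivery/pregnancy bundle inside CRG-1000: a dense, stereotyped episode.
  pregnancy_codes <- with_shared(list(
    "V27" = 0.85, "648" = 0.65, "650" = 0.65, "664" = 0.55, "401" = 0.45,
    "V22" = 0.50, "644" = 0.40, "646" = 0.45, "661" = 0.40, "663" = 0.40,
    "B03AA" = 0.75, "H03CA" = 0.65, "N02BB" = 0.50, "B03BB" = 0.45,
    "A12AA" = 0.50, "G02AB" = 0.40))
  # Hypertension with its cardiovascular/metabolic comorbidity bundle.
  hypertension_codes <- with_shared(list(
    "401" = 0.85, "272" = 0.50, "427" = 0.40, "414" = 0.40, "440" = 0.35,
    "278" = 0.40, "715" = 0.40, "530" = 0.35, "300" = 0.35,
    "C09AA" = 0.70, "C10AA" = 0.60, "C03AA" = 0.45, "C07AB" = 0.40,
    "C08CA" = 0.40, "A02BC" = 0.45))
  # Type-II-like diabetes: oral antihyperglycemics plus complications.
  diab_biguanide_codes <- with_shared(list(
    "250" = 0.85, "272" = 0.50, "401" = 0.25, "366" = 0.40, "362" = 0.30,
    "278" = 0.45, "443" = 0.35, "585" = 0.30, "357" = 0.40, "715" = 0.35,
    "A10BA" = 0.70, "C10AA" = 0.60, "A10BB" = 0.40, "A02BC" = 0.40,
    "B01AC" = 0.30, "C09AA" = 0.25))
  # Type-I-like diabetes: insulins, hypoglycemia and long-term-therapy codes.
  diab_insulin_codes <- with_shared(list(
    "250" = 0.85, "362" = 0.50, "585" = 0.35, "251" = 0.50, "337" = 0.40,
    "V58" = 0.55, "276" = 0.40, "564" = 0.40, "787" = 0.40,
    "A10AB" = 0.85, "A10AE" = 0.75, "A10AC" = 0.50, "A10AD" = 0.45,
    "H04AA" = 0.50, "V04CA" = 0.45))
  # Co-occurring diabetes and hypertension: both disease bundles plus the
  # dense cardiovascular-prevention therapy of older multimorbid patients.
  multimorbid_codes <- with_shared(list(
    "250" = 0.75, "401" = 0.80, "272" = 0.55, "427" = 0.55, "414" = 0.55,
    "440" = 0.45, "278" = 0.45, "530" = 0.35, "715" = 0.40, "585" = 0.40,
    "443" = 0.40, "366" = 0.35, "403" = 0.50,
    "C09AA" = 0.70, "C10AA" = 0.65, "A10BA" = 0.60, "C03AA" = 0.55,
    "C07AB" = 0.50, "C08CA" = 0.45, "B01AC" = 0.60, "A02BC" = 0.45,
    "A10BB" = 0.35, "A10BD" = 0.60, "C09BA" = 0.55, "C10BA" = 0.45))

  # Incidental (background) code utilization scales with morbidity: healthy
  # patients accrue the fewest off-profile codes, multimorbid ones the most.
  bg <- function(mult) background * mult

  # Chronic phenotypes carry a per-patient severity gradient on their
  # treatment/comorbidity codes (not on the defining lead codes or the shared
  # acute codes): mildly affected patients have sparser bundles, as in real
  # claims. The scaling is mean-preserving, so profile rates keep the design
  # values above.
  severity <- c(0.5, 1)
  graded_for <- function(codes, exempt) {
    setdiff(names(codes), c(exempt, names(shared)))
  }

  # The pregnancy/delivery bundle spans two CRGs, as pregnancy-induced
  # hypertension is classified under the hypertension CRG: one latent
  # "pregnancy" group drawing mostly from CRG-5192 and partly from CRG-1000.
  specs <- list(
    group_spec("CRG-1000", 46835, age_mean = 38, age_sd = 18, sex_ratio = 0.5,
               phenotypes = list(
                 healthy = list(weight = 0.975,
                                rates = make_rates(vocab, healthy_codes, bg(0.5))),
                 pregnancy = list(weight = 0.025, age_mean = 31, age_sd = 6,
                                  sex_ratio = 1,
                                  rates = make_rates(vocab, pregnancy_codes, bg(1))))),
    group_spec("CRG-5192", 12447, age_mean = 66, age_sd = 13, sex_ratio = 0.52,
               phenotypes = list(
                 hypertensive = list(weight = 0.92,
                                     rates = make_rates(vocab, hypertension_codes, bg(1)),
                                     severity_range = severity,
                                     graded_codes = graded_for(hypertension_codes, "401")),
                 pregnancy = list(weight = 0.08, age_mean = 31, age_sd = 6,
                                  sex_ratio = 1,
                                  rates = make_rates(vocab, pregnancy_codes, bg(1))))),
    group_spec("CRG-5424", 2166, age_mean = 64, age_sd = 12, sex_ratio = 0.47,
               phenotypes = list(
                 diabetic_biguanide = list(weight = 0.75,
                                           rates = make_rates(vocab, diab_biguanide_codes, bg(1)),
                                           severity_range = severity,
                                           graded_codes = graded_for(diab_biguanide_codes, "250")),
                 diabetic_insulin = list(weight = 0.25, age_mean = 35, age_sd = 15,
                                         rates = make_rates(vocab, diab_insulin_codes, bg(1)),
                                         severity_range = severity,
                                         graded_codes = graded_for(diab_insulin_codes,
                                                                   c("250", "A10AB")))))
  )
  if (case == 2) {
    specs <- c(specs, list(
      group_spec("CRG-6144", 3179, age_mean = 70, age_sd = 11, sex_ratio = 0.5,
                 phenotypes = list(
                   multimorbid = list(weight = 1,
                                      rates = make_rates(vocab, multimorbid_codes, bg(1.5)),
                                      severity_range = severity,
                                      graded_codes = graded_for(multimorbid_codes,
                                                                c("250", "401")))))))
  }
  specs
}

#' Generate a synthetic cohort
#'
#' Draws, for each group spec, patient sub-phenotypes by weight, then each of
#' the `D` binary code features as an independent Bernoulli draw at the
#' sub-phenotype's presence rate. Ages are normal, truncated at 0; sex is
#' Bernoulli at the female fraction. Bit-identical for a fixed seed.
#'
#' @param specs list of [group_spec()] objects sharing one vocabulary layout.
#' @param vocab the [code_vocabulary()] giving the feature order.
#' @param seed integer RNG seed.
#' @return an object of class `cohort`: list with integer matrix `X` (n x D),
#'   `crg`, `subgroup` (latent sub-phenotype, generator ground truth), `age`,
#'   `sex`, `patient_id`, `vocab`, `n`.
#' @export
generate_cohort <- function(specs, vocab, seed = 1) {
  stopifnot(is.list(specs), length(specs) >= 1)
  for (s in specs) {
    stopifnot(inherits(s, "group_spec"))
    for (ph in s$phenotypes) stopifnot(length(ph$rates) == vocab$D)
  }
  set.seed(as.integer(seed))

  blocks <- lapply(specs, function(s) {
    n <- s$n_patients
    w <- vapply(s$phenotypes, `[[`, 0, "weight")
    w <- w / sum(w)
    pheno <- sample(names(s$phenotypes), n, replace = TRUE, prob = w)
    X <- matrix(0L, nrow = n, ncol = vocab$D)
    age <- numeric(n)
    sex <- character(n)
    for (ph_name in names(s$phenotypes)) {
      ph <- s$phenotypes[[ph_name]]
      idx <- which(pheno == ph_name)
      m <- length(idx)
      if (m == 0) next
      # Per-patient severity scaling of the graded (treatment/comorbidity)
      # codes: mean-preserving, so profile rates keep their design values
      # while mildly affected patients carry sparser bundles.
      s_i <- NULL
      graded <- rep(FALSE, vocab$D)
      if (!is.null(ph$severity_range)) {
        lo <- ph$severity_range[1]; hi <- ph$severity_range[2]
        s_i <- runif(m, lo, hi) / ((lo + hi) / 2)
        graded <- if (is.null(ph$graded_codes)) {
          rep(TRUE, vocab$D)
        } else {
          vocab$codes %in% ph$graded_codes
        }
      }
      Xp <- matrix(0L, nrow = m, ncol = vocab$D)
      for (j in seq_len(vocab$D)) {
        pj <- if (graded[j]) pmin(1, ph$rates[j] * s_i) else ph$rates[j]
        Xp[, j] <- rbinom(m, 1L, pj)
      }
      X[idx, ] <- Xp
      mu <- if (!is.null(ph$age_mean)) ph$age_mean else s$age_mean
      sdv <- if (!is.null(ph$age_sd)) ph$age_sd else s$age_sd
      fr <- if (!is.null(ph$sex_ratio)) ph$sex_ratio else s$sex_ratio
      a <- rnorm(m, mu, sdv)
      while (any(a < 0)) a[a < 0] <- rnorm(sum(a < 0), mu, sdv)
      age[idx] <- a
      sex[idx] <- ifelse(rbinom(m, 1L, fr) == 1L, "F", "M")
    }
    list(X = X, crg = rep(s$crg_label, n), subgroup = pheno,
         age = age, sex = sex)
  })

  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  colnames(X) <- vocab$codes
  n <- nrow(X)
  ids <- sprintf("P%06d", seq_len(n))
  rownames(X) <- ids
  structure(list(X = X,
                 crg = unlist(lapply(blocks, `[[`, "crg"), use.names = FALSE),
                 subgroup = unlist(lapply(blocks, `[[`, "subgroup"), use.names = FALSE),
                 age = unlist(lapply(blocks, `[[`, "age"), use.names = FALSE),
                 sex = unlist(lapply(blocks, `[[`, "sex"), use.names = FALSE),
                 patient_id = ids, vocab = vocab, n = n),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort: n =", x$n, "patients, D =", x$vocab$D, "code features\n")
  print(table(x$crg))
  invisible(x)
}

# Subset a cohort by row indices, preserving rows unchanged.
cohort_subset <- function(cohort, idx) {
  structure(list(X = cohort$X[idx, , drop = FALSE],
                 crg = cohort$crg[idx], subgroup = cohort$subgroup[idx],
                 age = cohort$age[idx], sex = cohort$sex[idx],
                 patient_id = cohort$patient_id[idx],
                 vocab = cohort$vocab, n = length(idx)),
            class = "cohort")
}

#' Random under-sampling to the minority CRG size
#'
#' Every CRG is reduced by uniform sampling without replacement to the size of
#' the smallest CRG; retained patients' rows are unchanged. With the default
#' study sizes this yields 3 x 2,166 = 6,498 patients in case 1 and
#' 4 x 2,166 = 8,664 in case 2.
#'
#' @param cohort a [generate_cohort()] result.
#' @param seed integer RNG seed.
#' @return a balanced `cohort`.
#' @export
undersample <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  sizes <- table(cohort$crg)
  if (length(sizes) < 2) stop("under-sampling needs at least two CRGs")
  target <- min(sizes)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(names(sizes), function(g) {
    idx <- which(cohort$crg == g)
    if (length(idx) == target) idx else sort(sample(idx, target))
  }), use.names = FALSE)
  cohort_subset(cohort, sort(keep))
}

#' Random train/test split
#'
#' Disjoint, exhaustive partition with `floor(train_fraction * n)` training
#' patients; with the study's 75/25 split this reproduces test sizes of 1,625
#' (case 1, n = 6,498) and 2,166 (case 2, n = 8,664).
#'
#' @param cohort a `cohort`.
#' @param train_fraction fraction in (0, 1); default 0.75.
#' @param seed integer RNG seed.
#' @return list with `cohort` elements `train` and `test`.
#' @export
train_test_split <- function(cohort, train_fraction = 0.75, seed = 1) {
  stopifnot(inherits(cohort, "cohort"),
            train_fraction > 0, train_fraction < 1)
  if (cohort$n < 2) stop("need at least 2 patients to split")
  n_train <- floor(train_fraction * cohort$n)
  set.seed(as.integer(seed))
  tr <- sort(sample(cohort$n, n_train))
  list(train = cohort_subset(cohort, tr),
       test = cohort_subset(cohort, setdiff(seq_len(cohort$n), tr)))
}
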