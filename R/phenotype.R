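# Phenotype preparation: age shrinkage correction, within-sex
# standardization, pedigree kinship and heritability.

#' Quadratic age-shrinkage model for adult height
#'
#' Longitudinal data show adults begin to lose height around age 30, with the
#' rate of loss increasing linearly with age (constant acceleration).
#' Integrating a linear loss-rate model `dH/dAge = -slope * Age + intercept`
#' gives a quadratic loss `-(slope/2) * (Age - onset)^2` past the onset age
#' `intercept/slope`.  The defaults are the published loss-rate fits
#' (males: slope 0.00416 cm/yr^2, intercept 0.124 cm/yr; females: 0.00641 and
#' 0.18975), with the onset rounded to 30 years because ages are recorded in
#' full years.
#'
#' @param male,female numeric `c(slope, intercept)` of the loss-rate fit.
#' @param onset onset age actually used in the piecewise formula (years).
#' @return list of class `age_model` with elements `coef` (quadratic
#'   coefficients per sex, cm/yr^2), `onset`, and the derivation for each sex.
#' @export
age_model <- function(male = c(slope = 0.00416, intercept = 0.124),
                      female = c(slope = 0.00641, intercept = 0.18975),
                      onset = 30) {
  dm <- derive_age_model(male["slope"], male["intercept"])
  df <- derive_age_model(female["slope"], female["intercept"])
  structure(
    list(coef = c(male = unname(dm$coefficient), female = unname(df$coefficient)),
         onset = onset, male = dm, female = df),
    class = "age_model"
  )
}

#' Derive the quadratic shrinkage model from a linear loss-rate fit
#'
#' Given `dH/dAge = -slope * Age + intercept`, shrinkage starts when the rate
#' crosses zero (`onset = intercept/slope`) and integrating the rate with
#' `H(onset) = 0` gives the quadratic coefficient `slope/2`.
#'
#' @param slope loss-rate slope (cm/yr^2), must be > 0.
#' @param intercept loss-rate intercept (cm/yr).
#' @return list: `onset` (years, unrounded), `coefficient` (cm/yr^2).
#' @examples
#' derive_age_model(0.00416, 0.124)   # onset 29.8, coefficient 0.00208
#' @export
derive_age_model <- function(slope, intercept) {
  if (slope <= 0) stop("slope must be positive")
  list(onset = unname(intercept / slope), coefficient = unname(slope / 2))
}

#' Height lost to age-related shrinkage
#'
#' Piecewise quadratic: 0 up to the onset age, then
#' `-coef_sex * (age - onset)^2` (cm, always <= 0).
#'
#' @param age age in years (>= 0), vectorized.
#' @param sex `"male"`/`"female"`, vectorized.
#' @param model `age_model`.
#' @return numeric vector of losses in cm (<= 0).
#' @examples
#' height_loss(40, "male")    # -0.208
#' height_loss(50, "female")  # -1.282
#' @export
height_loss <- function(age, sex, model = age_model()) {
  if (any(age < 0)) stop("age must be non-negative")
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  sex <- rep_len(sex, length(age))
  over <- pmax(age - model$onset, 0)
  -model$coef[sex] * over^2
}

#' Correct measured heights for age and sex
#'
#' Combines technical repeats (mean by default), removes the expected
#' age-related shrinkage (i.e. adds the lost height back), and standardizes
#' within sex so that male and female heights are comparable z-scores.
#' Optionally the age correction can be a linear model re-fit from the data
#' itself (`height ~ sex + age`), or omitted.
#'
#' @param measurements long table (`iid`, `sex`, `age`, `height`, optionally
#'   `fid`, `rep`) as produced by [simulate_phenotypes()].
#' @param model `age_model` for the quadratic correction.
#' @param age_correction `"quadratic"` (default), `"linear"` (coefficient
#'   re-fit from the data), or `"none"`.
#' @param combine how repeats are combined: `"mean"` (default) or `"median"`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return data.frame of class `corrected_phenotype`: `iid`, `fid`, `sex`,
#'   `age`, `n_rep`, `height_mean`, `height_corrected`, `z`.  Persons with
#'   missing sex or age are dropped with a warning.
#' @export
correct_heights <- function(measurements, model = age_model(),
                            age_correction = c("quadratic", "linear", "none"),
                            combine = c("mean", "median"),
                            sd_type = c("sample", "population")) {
  age_correction <- match.arg(age_correction)
  combine <- match.arg(combine)
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("iid", "sex", "age", "height") %in% names(measurements)))

  bad <- is.na(measurements$sex) | is.na(measurements$age)
  if (any(bad)) {
    warning(sprintf("dropping %d measurement(s) with missing sex or age",
                    sum(bad)))
    measurements <- measurements[!bad, ]
  }
  fun <- if (combine == "mean") mean else stats::median
  agg <- stats::aggregate(height ~ iid, data = measurements, FUN = fun)
  names(agg)[2] <- "height_mean"
  nrep <- stats::aggregate(height ~ iid, data = measurements, FUN = length)
  first <- measurements[!duplicated(measurements$iid), ]
  out <- data.frame(
    iid = agg$iid,
    fid = if ("fid" %in% names(first)) first$fid[match(agg$iid, first$iid)] else NA,
    sex = first$sex[match(agg$iid, first$iid)],
    age = first$age[match(agg$iid, first$iid)],
    n_rep = nrep$height[match(agg$iid, nrep$iid)],
    height_mean = agg$height_mean
  )

  out$height_corrected <- switch(
    age_correction,
    quadratic = out$height_mean - height_loss(out$age, out$sex, model),
    linear = {
      fit <- stats::lm(height_mean ~ sex + age, data = out)
      b <- stats::coef(fit)["age"]
      out$height_mean - b * (out$age - mean(out$age))
    },
    none = out$height_mean
  )

  out$z <- NA_real_
  for (s in unique(out$sex)) {
    i <- out$sex == s
    x <- out$height_corrected[i]
    sdv <- if (sd_type == "sample") stats::sd(x) else
      sqrt(mean((x - mean(x))^2))
    out$z[i] <- (x - mean(x)) / sdv
  }
  class(out) <- c("corrected_phenotype", "data.frame")
  out
}

#' Additive relationship matrix from a pedigree
#'
#' Standard recursive (tabular) computation of expected additive relatedness,
#' i.e. twice the kinship coefficient: 1 on the diagonal for non-inbred
#' individuals, 0.5 for full siblings and parent-offspring, 0.125 for first
#' cousins, 0 for unrelated founders.
#'
#' @param ped pedigree (acyclic; founders are rows without parents).
#' @return symmetric numeric matrix with `iid` dimnames.
#' @export
kinship_from_pedigree <- function(ped) {
  ord <- .pedigree_order(ped)
  ids <- ped$iid[ord]
  fa <- match(ped$father[ord], ids)
  mo <- match(ped$mother[ord], ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    pf <- fa[i]; pm <- mo[i]
    A[i, i] <- 1 + if (!is.na(pf) && !is.na(pm)) 0.5 * A[pf, pm] else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      a_ij <- 0.5 * ((if (!is.na(pf)) A[j, pf] else 0) +
                       (if (!is.na(pm)) A[j, pm] else 0))
      A[i, j] <- a_ij
      A[j, i] <- a_ij
    }
  }
  A[ped$iid, ped$iid]
}

#' Narrow-sense heritability from pedigree relatedness
#'
#' Single-component REML fit (see [reml_fit()]) of the corrected phenotype on
#' the pedigree's additive-relationship matrix.  Returns the fraction of
#' phenotypic variance attributed to additive genetics and its standard
#' error.
#'
#' @param corrected `corrected_phenotype` table (uses `z`) or a named numeric
#'   vector of phenotypes.
#' @param A additive relationship matrix covering the phenotyped ids.
#' @param ... passed to [reml_fit()].
#' @return list: `h2`, `se`, and the underlying `fit`.
#' @export
pedigree_heritability <- function(corrected, A, ...) {
  y <- if (is.data.frame(corrected)) {
    stats::setNames(corrected$z, corrected$iid)
  } else corrected
  ids <- intersect(names(y), rownames(A))
  fit <- reml_fit(y[ids], list(additive = A[ids, ids]), ...)
  list(h2 = unname(fit$fractions["additive"]),
       se = unname(fit$fraction_se["additive"]),
       fit = fit)
}
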