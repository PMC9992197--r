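#' Published cohort summary statistics used by the clinical simulator
#'
#' Means and SDs of the clinical covariates of the cognitively impaired
#' (CI) and non-impaired (CNI) patient groups (24 subjects each), plus the
#' assumed healthy-control (HC) distributions. HC children carry no
#' epilepsy variables; their WISC-IV full-scale IQ is modelled as a
#' Gaussian centred on 100 confined to the normal 90-110 range (the only
#' constraint stated for controls), the other indices as N(100, 10).
#'
#' @return nested list keyed by group then variable: c(mean, sd).
#' @export
clinicalNorms <- function() {
  list(
    CI = list(
      sex_f_prob = 14 / 24,
      onset_age = c(7.98, 1.45),
      course_months = c(6.08, 4.14),
      seizure_count = c(3.17, 1.34),
      FSIQ = c(84.63, 4.79), VCI = c(82.96, 9.12), PRI = c(88.5, 10.44),
      WMI = c(88.29, 8.47), PSI = c(93.25, 15.88)
    ),
    CNI = list(
      sex_f_prob = 11 / 24,
      onset_age = c(8.80, 1.74),
      course_months = c(5.40, 7.75),
      seizure_count = c(3.125, 2.95),
      FSIQ = c(107.79, 8.03), VCI = c(104.96, 12.23), PRI = c(111.79, 7.37),
      WMI = c(100.79, 10.01), PSI = c(106.16, 14.54)
    ),
    HC = list(
      sex_f_prob = 0.5,
      age = c(8.35, 1.92),
      FSIQ = c(100, 5), VCI = c(100, 10), PRI = c(100, 10),
      WMI = c(100, 10), PSI = c(100, 10)
    )
  )
}

.rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  # inverse-CDF truncated normal draw (single value)
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(1, pl, pu), mean, sd)
}

.truncmoments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  fa <- stats::dnorm(al); fb <- stats::dnorm(be)
  m <- mu + sigma * (fa - fb) / Z
  al0 <- if (is.finite(al)) al else 0; be0 <- if (is.finite(be)) be else 0
  v <- sigma^2 * (1 + (al0 * fa - be0 * fb) / Z - ((fa - fb) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

.parent_cache <- new.env(parent = emptyenv())

# parent (mu, sigma) such that the (a,b)-truncated normal has the target
# mean/sd: the published group statistics describe the truncation-defined
# group itself, not an untruncated parent
.truncnorm_parent <- function(mean, sd, lower, upper) {
  key <- paste(signif(c(mean, sd, lower, upper), 12), collapse = "|")
  hit <- .parent_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mm <- .truncmoments(par[1], exp(par[2]), lower, upper)
    (mm["mean"] - mean)^2 / sd^2 + (mm["sd"] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  out <- c(fit$par[1], exp(fit$par[2]))
  .parent_cache[[key]] <- out
  out
}

#' Draw one subject's clinical record
#'
#' Covariates are drawn independently from Gaussians with the published
#' group means/SDs, truncated where the group definition demands it:
#' CI implies FSIQ < 90, CNI implies FSIQ > 90, HC lies in 90-110.
#' Epilepsy variables (onset age, course, seizure count) exist only for
#' patient groups; seizure counts are rounded to non-negative integers.
#'
#' @param group one of "CI", "CNI", "HC".
#' @param subjectId subject identifier string.
#' @param norms summary statistics, see [clinicalNorms()].
#' @return one-row data.frame (a SubjectRecord).
#' @examples
#' set.seed(1); sampleClinical("CI", "sub-001")
#' @export
sampleClinical <- function(group, subjectId = NULL, norms = clinicalNorms()) {
  if (!group %in% c("CI", "CNI", "HC"))
    stop("unknown group label: ", group)
  g <- norms[[group]]
  sex <- if (stats::runif(1) < g$sex_f_prob) "F" else "M"
  wisc_lim <- switch(group,
                     CI = c(40, 90 - 1e-9),
                     CNI = c(90 + 1e-9, 160),
                     HC = c(90, 110))
  fp <- .truncnorm_parent(g$FSIQ[1], g$FSIQ[2], wisc_lim[1], wisc_lim[2])
  FSIQ <- .rtruncnorm1(fp[1], fp[2], wisc_lim[1], wisc_lim[2])
  idx <- vapply(c("VCI", "PRI", "WMI", "PSI"),
                function(v) .rtruncnorm1(g[[v]][1], g[[v]][2], lower = 1),
                numeric(1))
  if (group == "HC") {
    onset <- NA_real_; course <- NA_real_; seiz <- NA_integer_
    age <- .rtruncnorm1(g$age[1], g$age[2], lower = 4)
  } else {
    onset <- .rtruncnorm1(g$onset_age[1], g$onset_age[2], lower = 1)
    course <- .rtruncnorm1(g$course_months[1], g$course_months[2], lower = 0.5)
    seiz <- max(0L, as.integer(round(stats::rnorm(1, g$seizure_count[1],
                                                  g$seizure_count[2]))))
    age <- onset + course / 12
  }
  data.frame(
    subject_id = if (is.null(subjectId)) NA_character_ else subjectId,
    group = group, sex = sex, age = age,
    onset_age = onset, course_months = course, seizure_count = seiz,
    FSIQ = FSIQ, VCI = idx[["VCI"]], PRI = idx[["PRI"]],
    WMI = idx[["WMI"]], PSI = idx[["PSI"]],
    stringsAsFactors = FALSE)
}

#' Draw a full cohort manifest
#'
#' @param design a [CohortDesign-class].
#' @param groups group labels to include.
#' @return data.frame with one SubjectRecord row per subject.
#' @export
sampleCohortManifest <- function(design, groups = c("CI", "CNI", "HC")) {
  p <- designParams(design)
  rows <- list()
  i <- 0L
  for (g in groups) {
    for (k in seq_len(p$nPerGroup)) {
      i <- i + 1L
      set.seed(.subject_seed(p$seed, i, stream = 1L))
      rows[[i]] <- sampleClinical(g, sprintf("sub-%s-%02d", g, k))
    }
  }
  do.call(rbind, rows)
}

# deterministic per-subject sub-seed below 2^31
.subject_seed <- function(master, index, stream = 0L) {
  as.integer((as.numeric(master) * 48271 + index * 7919 +
                stream * 1299721) %% 2147483629)
}
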