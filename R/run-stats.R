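#' Run the full statistics layer on a relative-power table
#'
#' Per (ROI, band): a Kruskal-Wallis omnibus comparison of the groups,
#' pairwise Mann-Whitney post hoc tests with Bonferroni adjustment over
#' the pairs, and Benjamini-Hochberg FDR control within the reporting
#' family — by default all 26 ROIs within one band (and, for pairwise
#' rows, one contrast). Clinical correlations (onset age, epilepsy
#' course, seizure count against each cell's relative power) are computed
#' within each patient group with the Pearson/Spearman gate and FDR
#' correction over ROIs within each (group, variable, band) family.
#'
#' @param table a [RelativePowerTable-class].
#' @param manifest cohort manifest data.frame (columns subject_id, group,
#'   and the clinical covariates).
#' @param alpha significance level (default 0.05).
#' @param reportingCut stricter reporting threshold (default 0.005).
#' @param fdrFamily "per-band" (default) or "global".
#' @param clinicalVars clinical covariates to correlate.
#' @return a [StatReport-class].
#' @export
runStats <- function(table, manifest, alpha = 0.05, reportingCut = 0.005,
                     fdrFamily = c("per-band", "global"),
                     clinicalVars = c("onset_age", "course_months",
                                      "seizure_count")) {
  fdrFamily <- match.arg(fdrFamily)
  v <- powerValues(table)
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)
    dn <- dimnames(v)
    stop("missing relative-power cells, e.g. ",
         paste(dn[[1]][bad[1, 1]], dn[[2]][bad[1, 2]], dn[[3]][bad[1, 3]],
               collapse = " "),
         " (", nrow(bad), " cells)")
  }
  subs <- dimnames(v)[[1]]
  rois <- dimnames(v)[[2]]
  bands <- dimnames(v)[[3]]
  m <- manifest[match(subs, manifest$subject_id), , drop = FALSE]
  if (any(is.na(m$group)))
    stop("manifest is missing subjects: ",
         paste(subs[is.na(m$group)], collapse = ", "))
  groups <- factor(m$group)

  rows <- vector("list", length(rois) * length(bands))
  ri <- 0L
  for (b in bands) {
    for (ro in rois) {
      x <- v[, ro, b]
      kw <- kruskalWallis(x, groups)
      ph <- pairwisePosthoc(x, groups)
      ri <- ri + 1L
      rows[[ri]] <- rbind(
        data.frame(roi = ro, band = b, contrast = "omnibus", H = kw$H,
                   p_raw = kw$p, p_bonf = NA_real_, stringsAsFactors = FALSE),
        data.frame(roi = ro, band = b, contrast = ph$contrast, H = NA_real_,
                   p_raw = ph$p_raw, p_bonf = ph$p_bonf,
                   stringsAsFactors = FALSE))
    }
  }
  tests <- do.call(rbind, rows)

  # FDR: omnibus rows on p_raw, pairwise rows on the Bonferroni p,
  # each within its (band x contrast) family (or one global family)
  tests$p_fdr <- NA_real_
  famKey <- if (fdrFamily == "per-band")
    paste(tests$band, tests$contrast) else tests$contrast
  for (key in unique(famKey)) {
    sel <- famKey == key
    pin <- ifelse(is.na(tests$p_bonf[sel]), tests$p_raw[sel],
                  tests$p_bonf[sel])
    tests$p_fdr[sel] <- bhFdr(pin, q = alpha)$adjusted
  }
  tests$reject_05 <- tests$p_fdr <= alpha
  tests$reject_005 <- ifelse(is.na(tests$p_bonf),
                             tests$p_raw <= reportingCut,
                             tests$p_bonf <= reportingCut)

  # clinical correlations within each patient group
  cors <- list(); ci <- 0L
  for (g in intersect(c("CI", "CNI"), levels(groups))) {
    gi <- which(groups == g)
    for (var in clinicalVars) {
      cv <- m[[var]][gi]
      if (is.null(cv) || sum(is.finite(cv)) < 4) next
      if (stats::sd(cv[is.finite(cv)]) == 0) next
      for (b in bands) {
        res <- lapply(rois, function(ro)
          clinicalCorrelation(cv, v[gi, ro, b]))
        ci <- ci + 1L
        cors[[ci]] <- data.frame(
          group = g, variable = var, roi = rois, band = b,
          R = vapply(res, `[[`, numeric(1), "R"),
          p = vapply(res, `[[`, numeric(1), "p"),
          p_fdr = bhFdr(vapply(res, `[[`, numeric(1), "p"), q = alpha)$adjusted,
          method = vapply(res, `[[`, character(1), "method"),
          stringsAsFactors = FALSE)
      }
    }
  }
  correlations <- if (length(cors)) do.call(rbind, cors) else
    data.frame(group = character(), variable = character(),
               roi = character(), band = character(), R = numeric(),
               p = numeric(), p_fdr = numeric(), method = character())
  rownames(tests) <- NULL
  new("StatReport", tests = tests, correlations = correlations,
      settings = list(alpha = alpha, reporting_cut = reportingCut,
                      fdr_family = fdrFamily, groups = levels(groups),
                      n_subjects = length(subs)))
}

#' FDR rejection set for one band and contrast
#'
#' @param report a [StatReport-class].
#' @param band band name. @param contrast contrast name, e.g. "CI-HC".
#' @param alpha rejection level on the FDR-adjusted p.
#' @return character vector of rejected ROI names.
#' @export
rejectedRois <- function(report, band, contrast, alpha = 0.05) {
  t <- statTests(report)
  sel <- t$band == band & t$contrast == contrast & t$p_fdr <= alpha
  t$roi[sel]
}

#' Write / read a StatReport as CSV
#'
#' `writeStatReport` writes `<stem>_tests.csv`, `<stem>_correlations.csv`
#' and `<stem>_settings.json`; the round trip through
#' `readStatReport(stem)` is lossless up to numeric formatting.
#'
#' @param report a [StatReport-class]. @param stem path stem.
#' @return `readStatReport` returns a [StatReport-class].
#' @export
writeStatReport <- function(report, stem) {
  utils::write.csv(statTests(report), paste0(stem, "_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(statCorrelations(report),
                   paste0(stem, "_correlations.csv"), row.names = FALSE)
  jsonlite::write_json(report@settings, paste0(stem, "_settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname writeStatReport
#' @export
readStatReport <- function(stem) {
  tests <- utils::read.csv(paste0(stem, "_tests.csv"),
                           stringsAsFactors = FALSE)
  cors <- utils::read.csv(paste0(stem, "_correlations.csv"),
                          stringsAsFactors = FALSE)
  settings <- jsonlite::read_json(paste0(stem, "_settings.json"),
                                  simplifyVector = TRUE)
  new("StatReport", tests = tests, correlations = cors,
      settings = as.list(settings))
}

#' Heatmap-style matrix export of group differences
#'
#' One CSV per contrast: ROIs x bands matrix of FDR-adjusted p-values,
#' mirroring a significance heat map as plain data.
#'
#' @param report a [StatReport-class]. @param dir output directory.
#' @return invisible vector of written paths.
#' @export
writeContrastMatrices <- function(report, dir) {
  t <- statTests(report)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (ct in setdiff(unique(t$contrast), "omnibus")) {
    sub <- t[t$contrast == ct, ]
    mat <- stats::xtabs(p_fdr ~ roi + band, data = sub)
    path <- file.path(dir, paste0("pfdr_", gsub("[^A-Za-z]", "_", ct), ".csv"))
    utils::write.csv(as.data.frame.matrix(mat), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
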