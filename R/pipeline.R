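#' Configuration for an end-to-end synthetic-study analysis
#'
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @param n_sires,dams_per_sire,offspring_per_dam,n_generations breeding
#'   design passed to [simulate_pedigree()].
#' @param behaviour optional [trait_model()] override.
#' @param cort a [cortisol_gxe_model()].
#' @param design a [study_design()].
#' @param include_all phenotype every fish for every assay.
#' @param behaviour_traits traits run through the univariate ladder.
#' @param g_traits traits entering the multivariate G model (cortisol
#'   contexts are merged into one repeated trait; emergence is sign-flipped).
#' @param fixed fixed-effects formula for the behavioural models.
#' @param n_boot bootstrap replicates for the eigen intervals (0 disables).
#' @param out_dir directory for report files (`NULL`: no files written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_sires = 12, dams_per_sire = 4,
                            offspring_per_dam = 12, n_generations = 3,
                            behaviour = NULL, cort = cortisol_gxe_model(),
                            design = study_design(), include_all = TRUE,
                            behaviour_traits = c("rel_area", "time_in_middle",
                                                 "track_length",
                                                 "sqrt_freezings",
                                                 "ln_emergence", "shoaling"),
                            g_traits = c("rel_area", "time_in_middle",
                                         "track_length", "sqrt_freezings",
                                         "neg_ln_emergence", "ln_cortisol"),
                            fixed = ~ rep + order_caught_z + temperature_z +
                              time_of_day_z + age_z + sex,
                            n_boot = 0, out_dir = NULL) {
  structure(list(seed = seed, n_sires = n_sires,
                 dams_per_sire = dams_per_sire,
                 offspring_per_dam = offspring_per_dam,
                 n_generations = n_generations, behaviour = behaviour,
                 cort = cort, design = design, include_all = include_all,
                 behaviour_traits = behaviour_traits, g_traits = g_traits,
                 fixed = fixed, n_boot = n_boot, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Only scalar fields are supported in the file (seed, design sizes,
#' bootstrap settings and cortisol parameters); matrix-valued overrides are
#' supplied programmatically.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  yml <- yaml::read_yaml(path)
  cort_args <- yml$cort %||% list()
  args <- yml[setdiff(names(yml), "cort")]
  args$cort <- do.call(cortisol_gxe_model, cort_args)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Univariate animal-model ladder
#'
#' For each behavioural trait (and optionally ln cortisol), fits the full
#' univariate animal model (additive genetic + permanent environment +
#' group + residual) and the reduced model without the genetic term, and
#' tests the genetic variance by a boundary-mixture likelihood-ratio test.
#'
#' @param study a [simulate_study()] result (or a compatible list with
#'   `phenotypes` and `A`).
#' @param traits traits to fit.
#' @param fixed fixed-effects formula.
#' @param se compute component standard errors.
#' @param control [qg_control()].
#' @return data frame, one row per trait: components, h2 (with SE),
#'   repeatability, LRT statistic and p-value; fits attached as attribute
#'   `"fits"`.
#' @export
run_univariate_ladder <- function(study, traits = NULL,
                                  fixed = ~ rep + order_caught_z +
                                    temperature_z + time_of_day_z + age_z +
                                    sex,
                                  se = TRUE, control = qg_control()) {
  ph <- study$phenotypes
  if (is.null(traits)) {
    traits <- setdiff(unique(ph$trait), c("ln_cortisol1", "ln_cortisol3"))
  }
  fits <- list()
  rows <- list()
  for (tr in traits) {
    d <- ph[ph$trait == tr & !is.na(ph$value), , drop = FALSE]
    full <- reml_fit(d, tr, fixed = fixed, A = study$A,
                     random = list(genetic = "us", pe = "us", group = "us"),
                     se = se, control = control)
    red <- reml_fit(d, tr, fixed = fixed, A = study$A,
                    random = list(pe = "us", group = "us"),
                    control = control)
    tst <- lrt(full, red, boundary = TRUE)
    comp <- vapply(full$components, function(S) S[1, 1], numeric(1))
    h2 <- heritability(full)
    rep_ <- repeatability(full)
    se_of <- function(key) {
      if (is.null(full$component_se)) return(NA_real_)
      k <- paste0(key, ":", tr, ",", tr)
      if (k %in% names(full$component_se)) full$component_se[[k]] else NA_real_
    }
    rows[[tr]] <- data.frame(
      trait = tr,
      va = comp[["genetic"]], va_se = se_of("genetic"),
      vpe = comp[["pe"]], vpe_se = se_of("pe"),
      vgroup = comp[["group"]], vgroup_se = se_of("group"),
      vresidual = comp[["residual"]], vresidual_se = se_of("residual"),
      h2 = h2$estimate, h2_se = h2$se,
      repeatability = rep_$estimate,
      chi2 = tst$statistic, p = tst$p_value,
      stringsAsFactors = FALSE
    )
    fits[[tr]] <- list(full = full, reduced = red, test = tst)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Multivariate animal model for G
#'
#' Builds the data for the multivariate G model — behavioural traits plus
#' cortisol treated as a single repeated trait with a context fixed effect,
#' emergence time sign-flipped so high values mean fast emergence, and all
#' traits standardised to SD units — then fits the full model (unstructured
#' G, PE, GROUP; residual covariance only among co-observed traits) and the
#' reduced model with a diagonal G, giving the overall genetic-integration
#' LRT. The fitted G is eigen-decomposed and, optionally, parametric
#' bootstrap intervals are attached.
#'
#' @inheritParams run_univariate_ladder
#' @param g_traits traits entering G.
#' @param n_boot bootstrap replicates (0 = none).
#' @param seed seed for the bootstrap stage.
#' @return list with `fit`, `fit_diag`, `integration_test`, `G`,
#'   `correlations`, `eigen` (with intervals when bootstrapped), `boot`.
#' @export
run_multivariate_g <- function(study, g_traits = c("rel_area",
                                                   "time_in_middle",
                                                   "track_length",
                                                   "sqrt_freezings",
                                                   "neg_ln_emergence",
                                                   "ln_cortisol"),
                               fixed = ~ rep + order_caught_z +
                                 temperature_z + sex,
                               n_boot = 0, seed = 1, se = FALSE,
                               control = qg_control()) {
  d <- .build_g_data(study, g_traits)
  oft <- intersect(c("rel_area", "time_in_middle", "track_length",
                     "sqrt_freezings"), g_traits)
  blocks <- if (length(oft) > 1) list(oft) else NULL
  fixed_list <- stats::setNames(rep(list(fixed), length(g_traits)), g_traits)
  if ("ln_cortisol" %in% g_traits) {
    fixed_list$ln_cortisol <- ~ context + order_caught_z + temperature_z + sex
  }
  full <- reml_fit(d, g_traits, fixed = fixed_list, A = study$A,
                   random = list(genetic = "us", pe = "us", group = "us"),
                   residual_blocks = blocks, engine = "generic",
                   se = se, control = control)
  diag_start <- .diag_g_start(full)
  red <- reml_fit(d, g_traits, fixed = fixed_list, A = study$A,
                  random = list(genetic = "diag", pe = "us", group = "us"),
                  residual_blocks = blocks, engine = "generic",
                  start = diag_start, control = control)
  tst <- lrt(full, red)

  ## G in SD units of the analysed (transformed) traits
  sds <- full$frame$sds
  Dinv <- diag(1 / sds, length(sds))
  G <- Dinv %*% full$components$genetic %*% Dinv
  dimnames(G) <- dimnames(full$components$genetic)
  es <- eigen_decomposition(G)
  boot <- NULL
  if (n_boot > 0) {
    boot <- parametric_bootstrap(full, n_reps = n_boot, seed = seed)
    ## replicate G matrices to SD units of their own fits are already
    ## back-scaled to data units; rescale by the point fit's SDs for
    ## comparability
    boot$G <- lapply(boot$G, function(Gr) {
      if (is.null(Gr)) return(NULL)
      out <- Dinv %*% Gr %*% Dinv
      dimnames(out) <- dimnames(Gr)
      out
    })
    es <- loading_intervals(boot, es)
  }
  list(fit = full, fit_diag = red, integration_test = tst, G = G,
       correlations = genetic_correlations(G), eigen = es, boot = boot)
}

## long data for the G model: merge cortisol contexts, negate ln emergence
.build_g_data <- function(study, g_traits) {
  ph <- study$phenotypes
  parts <- list()
  beh <- setdiff(g_traits, c("neg_ln_emergence", "ln_cortisol"))
  parts$beh <- ph[ph$trait %in% beh, , drop = FALSE]
  if ("neg_ln_emergence" %in% g_traits) {
    em <- ph[ph$trait == "ln_emergence", , drop = FALSE]
    if (nrow(em) > 0) {
      em$value <- -em$value
      em$trait <- "neg_ln_emergence"
      parts$em <- em
    }
  }
  if ("ln_cortisol" %in% g_traits) {
    co <- ph[ph$trait %in% c("ln_cortisol1", "ln_cortisol3"), , drop = FALSE]
    if (nrow(co) > 0) {
      co$context <- factor(ifelse(co$trait == "ln_cortisol1", "1", "3"))
      co$trait <- "ln_cortisol"
      ## the two contexts are separate sampling occasions of one trait
      co$occasion <- paste0(co$occasion, "_c", co$context)
      parts$co <- co
    }
  }
  cols <- Reduce(union, lapply(parts, names))
  d <- do.call(rbind, lapply(parts, function(x) {
    for (mc in setdiff(cols, names(x))) x[[mc]] <- NA
    x[, cols]
  }))
  if ("context" %in% names(d)) {
    d$context[is.na(d$context)] <- "1"  # unused level for non-cortisol rows
  }
  d <- d[!is.na(d$value), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## map the full fit's parameters to a diagonal-G start vector
.diag_g_start <- function(full) {
  info <- full$par_info
  fr <- full$frame
  gidx <- info$term.genetic$idx
  L <- .struct_load("us", fr$t, full$par[gidx])
  v <- pmax(diag(tcrossprod(L)), 1e-8)
  c(0.5 * log(v), full$par[-gidx])
}

#' Run the complete analysis pipeline on a synthetic study
#'
#' Simulates a study from the configuration, runs the univariate ladder,
#' the cortisol GxE model sequence and (optionally) the multivariate G model
#' with eigen decomposition and bootstrap, and writes report tables when an
#' output directory is configured.
#'
#' @param config a [pipeline_config()].
#' @param stages which stages to run.
#' @return object of class `qg_report`: list with `study`, `univariate`,
#'   `gxe`, `multivariate`, `config`.
#' @export
run_study_pipeline <- function(config = pipeline_config(),
                               stages = c("univariate", "gxe",
                                          "multivariate")) {
  ped <- simulate_pedigree(n_generations = config$n_generations,
                           n_sires = config$n_sires,
                           dams_per_sire = config$dams_per_sire,
                           offspring_per_dam = config$offspring_per_dam,
                           seed = config$seed + 1)
  study <- simulate_study(ped = ped, behaviour = config$behaviour,
                          cort = config$cort, design = config$design,
                          seed = config$seed,
                          include_all = config$include_all)
  out <- list(study = study, config = config)
  if ("univariate" %in% stages) {
    out$univariate <- run_univariate_ladder(
      study, traits = intersect(config$behaviour_traits,
                                unique(study$phenotypes$trait)),
      fixed = config$fixed)
  }
  if ("gxe" %in% stages) {
    out$gxe <- gxe_model_sequence(
      study$phenotypes, study$A,
      fixed = ~ order_caught_z + temperature_z + time_of_day_z + age_z +
        sex + body_mass_z + sex:body_mass_z)
  }
  if ("multivariate" %in% stages) {
    g_traits <- config$g_traits
    if (!is.null(out$univariate)) {
      ## drop traits with no detectable genetic variance (boundary estimates)
      zero_va <- out$univariate$trait[out$univariate$va <
                                        1e-6 * (out$univariate$va +
                                                  out$univariate$vresidual)]
      drop <- intersect(g_traits, zero_va)
      if (length(drop) > 0) {
        message("excluding zero-Va trait(s) from G: ",
                paste(drop, collapse = ", "))
        g_traits <- setdiff(g_traits, drop)
      }
    }
    out$multivariate <- run_multivariate_g(study, g_traits = g_traits,
                                           n_boot = config$n_boot,
                                           seed = config$seed + 1000)
  }
  class(out) <- "qg_report"
  if (!is.null(config$out_dir)) emit_report(out, config$out_dir)
  out
}

#' Write report tables for a pipeline run
#'
#' Emits CSV tables (univariate components, G covariance-correlation matrix,
#' eigen summary with intervals, ellipse coordinates for each trait pair
#' with cortisol) plus a JSON run summary with seeds and convergence
#' information.
#'
#' @param report a `qg_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
emit_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = report$config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               package_version = as.character(utils::packageVersion("qgstress")))
  if (!is.null(report$univariate)) {
    utils::write.csv(report$univariate,
                     file.path(dir, "univariate_components.csv"),
                     row.names = FALSE)
    meta$univariate_traits <- report$univariate$trait
  }
  if (!is.null(report$gxe)) {
    gx <- report$gxe
    gxdf <- data.frame(
      quantity = c("va1", "va3", "ra13", "h2_1", "h2_3",
                   "chi2_genetic", "p_genetic", "chi2_gxe", "p_gxe",
                   "chi2_corr", "p_corr"),
      value = c(gx$estimates$va, gx$estimates$ra13, gx$estimates$h2,
                gx$tests$genetic$statistic, gx$tests$genetic$p_value,
                gx$tests$gxe_variance$statistic,
                gx$tests$gxe_variance$p_value,
                gx$tests$correlation$statistic,
                gx$tests$correlation$p_value))
    utils::write.csv(gxdf, file.path(dir, "gxe_sequence.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$multivariate)) {
    mv <- report$multivariate
    utils::write.csv(mv$G, file.path(dir, "G_matrix.csv"))
    utils::write.csv(mv$correlations,
                     file.path(dir, "G_correlations.csv"))
    es <- mv$eigen
    edf <- data.frame(axis = rep(colnames(es$vectors),
                                 each = length(es$traits)),
                      trait = rep(es$traits, times = length(es$values)),
                      loading = as.numeric(es$vectors))
    if (!is.null(es$loading_lo)) {
      edf$lo <- as.numeric(es$loading_lo)
      edf$hi <- as.numeric(es$loading_hi)
    }
    utils::write.csv(edf, file.path(dir, "eigen_loadings.csv"),
                     row.names = FALSE)
    pdf_ <- data.frame(axis = colnames(es$vectors),
                       eigenvalue = es$values,
                       proportion = es$proportions)
    if (!is.null(es$prop_lo)) {
      pdf_$lo <- es$prop_lo
      pdf_$hi <- es$prop_hi
    }
    utils::write.csv(pdf_, file.path(dir, "eigen_proportions.csv"),
                     row.names = FALSE)
    if ("ln_cortisol" %in% rownames(mv$G)) {
      others <- setdiff(rownames(mv$G), "ln_cortisol")
      ell <- do.call(rbind, lapply(others, function(tr) {
        pts <- confidence_ellipse(mv$G[c("ln_cortisol", tr),
                                       c("ln_cortisol", tr)])
        data.frame(trait = tr, x = pts[, 1], y = pts[, 2])
      }))
      utils::write.csv(ell, file.path(dir, "genetic_ellipses.csv"),
                       row.names = FALSE)
    }
    meta$integration_chi2 <- mv$integration_test$statistic
    meta$integration_df <- mv$integration_test$df
    meta$integration_p <- mv$integration_test$p_value
    meta$bootstrap_converged <- if (!is.null(mv$boot)) {
      sum(mv$boot$converged)
    } else 0
  }
  jsonlite::write_json(meta, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.qg_report <- function(x, ...) {
  cat("qgstress pipeline report (seed ", x$config$seed, ")\n", sep = "")
  if (!is.null(x$univariate)) {
    cat("univariate ladder:\n")
    print(x$univariate[, c("trait", "va", "h2", "h2_se", "chi2", "p")])
  }
  if (!is.null(x$gxe)) print(x$gxe)
  if (!is.null(x$multivariate)) {
    cat("genetic integration LRT: ")
    print(x$multivariate$integration_test)
    print(x$multivariate$eigen)
  }
  invisible(x)
}
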