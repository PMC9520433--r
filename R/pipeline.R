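# End-to-end study orchestration: per-cluster x per-sex-stratum x
# per-trauma-category fits of models 1-4, liability conversion, LRT
# tables, cross-cluster meta-analysis and prevalence sensitivity runs,
# from one declarative configuration. Failures in individual grid cells
# are recorded and the grid continues.

#' Study configuration
#'
#' Declares the full analysis grid. The meta-analysis method has no
#' silent default: it must be stated.
#'
#' @param sim A [sim_config()] (simulation mode), or NULL when `paths`
#'   supply real inputs.
#' @param paths Optional named list of input paths: `plink_prefix`
#'   (bed/bim/fam genotypes), `trauma_items` (GCTA-style table of item
#'   responses), `item_categories` (two-column header-less table:
#'   item_id, category — one row per item column, in order),
#'   `phenotype` (GCTA-style), `covariates` (GCTA-style with value
#'   columns age, sex, batch in that order), `cluster` (GCTA-style
#'   cluster labels), `sex` (GCTA-style, F/M).
#' @param trauma_categories Subset of
#'   `c("full", "childhood", "adult", "catastrophic")`.
#' @param pc_mode `"all_pcs"` or `"pc1_only"`: how many trauma PCs enter
#'   the environmental relationship matrix.
#' @param precorrect Remove the genetic component (model-1 BLUP) from
#'   each trauma PC before building E.
#' @param unrelated_only Restrict each cluster to individuals with all
#'   pairwise relatedness below `unrelated_threshold`.
#' @param unrelated_threshold Relatedness cutoff (default 0.05).
#' @param strata Which sex strata to analyze: subset of
#'   `c("joint", "F", "M")`.
#' @param models Which of models 1-4 to fit.
#' @param prevalence_map Named list mapping stratum (`joint`, `F`, `M`)
#'   to the population prevalence used for liability conversion of a
#'   binary outcome; required for every requested stratum when the
#'   outcome is binary.
#' @param sensitivity_prevalences Optional numeric vector of alternative
#'   prevalences for sensitivity conversion.
#' @param n_grm_pcs Number of full-sample GRM principal components used
#'   as fixed covariates (default 15).
#' @param meta_method Pooling method (`"fixed"`, `"random_DL"`,
#'   `"random_REML"`); required, no default.
#' @param seed Integer master seed.
#' @param out_dir Optional directory: result tables and a run manifest
#'   are written there.
#' @return Object of class `study_config`.
#' @export
study_config <- function(sim = NULL, paths = NULL,
                         trauma_categories = "full",
                         pc_mode = c("all_pcs", "pc1_only"),
                         precorrect = FALSE,
                         unrelated_only = FALSE,
                         unrelated_threshold = 0.05,
                         strata = "joint",
                         models = 1:4,
                         prevalence_map = NULL,
                         sensitivity_prevalences = NULL,
                         n_grm_pcs = 15L,
                         meta_method, seed = 1L, out_dir = NULL) {
  pc_mode <- match.arg(pc_mode)
  if (missing(meta_method))
    stop("meta_method must be stated explicitly ('fixed', 'random_DL' or ",
         "'random_REML'); there is no silent default", call. = FALSE)
  meta_method <- match.arg(meta_method, c("fixed", "random_DL",
                                          "random_REML"))
  if (is.null(sim) && is.null(paths))
    stop("either a simulation config or input paths are required",
         call. = FALSE)
  stopifnot(all(trauma_categories %in%
                  c("full", "childhood", "adult", "catastrophic")),
            all(strata %in% c("joint", "F", "M")),
            all(models %in% 1:4))
  structure(list(sim = sim, paths = paths,
                 trauma_categories = trauma_categories, pc_mode = pc_mode,
                 precorrect = precorrect, unrelated_only = unrelated_only,
                 unrelated_threshold = unrelated_threshold,
                 strata = strata, models = sort(unique(models)),
                 prevalence_map = prevalence_map,
                 sensitivity_prevalences = sensitivity_prevalences,
                 n_grm_pcs = check_count(n_grm_pcs, "n_grm_pcs"),
                 meta_method = meta_method, seed = as.integer(seed),
                 out_dir = out_dir), class = "study_config")
}

# Assemble the analysis inputs either by simulation or from files.
load_study_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- child_seed(config$seed, "cohort")
    genotypes <- simulate_genotypes(sim)
    trauma <- simulate_trauma(genotypes, sim)
    grm_full <- compute_grm(genotypes)
    strata <- assign_strata(sim)
    # item categories: round-robin over the three subtypes
    item_cats <- rep_len(c("childhood", "adult", "catastrophic"),
                         ncol(trauma$items))
    # generative E: the full-sample all-PC item ERM, so the kernels the
    # pipeline later fits are the generative ones (well-specified run)
    pcs_gen <- compute_trauma_pcs(trauma$items)
    erm_gen <- compute_erm(pcs_gen)
    cohort <- simulate_phenotype(genotypes, trauma, sim, grm = grm_full,
                                 erm = erm_gen, e_mode = "kernel",
                                 strata = strata)
    list(genotypes = genotypes, items = trauma$items,
         item_categories = item_cats, phenotype = cohort$phenotype,
         covariates = cohort$covariates, cluster = cohort$cluster,
         sex = cohort$sex, sample_ids = genotypes$sample_ids,
         grm_full = grm_full, cohort = cohort)
  } else {
    p <- config$paths
    genotypes <- read_plink(p$plink_prefix)
    items_df <- read_gcta_table(p$trauma_items)
    items <- as.matrix(items_df[, -(1:2), drop = FALSE])
    rownames(items) <- items_df$IID
    # category map: item_id <tab> category, rows in item column order
    cats <- utils::read.table(p$item_categories, header = FALSE,
                              colClasses = "character")
    if (nrow(cats) != ncol(items))
      stop("item_categories must have one row per trauma item column",
           call. = FALSE)
    colnames(items) <- cats[[1]]
    pheno <- read_gcta_table(p$phenotype)
    covar <- read_gcta_table(p$covariates)
    cluster <- read_gcta_table(p$cluster)
    sex <- read_gcta_table(p$sex)
    ids <- genotypes$sample_ids
    reorder <- function(df) df[match(ids, df$IID), , drop = FALSE]
    list(genotypes = genotypes, items = items[match(ids, rownames(items)), ,
                                              drop = FALSE],
         item_categories = cats[[2]],
         phenotype = reorder(pheno)[[3]],
         covariates = stats::setNames(
           reorder(covar)[, -(1:2), drop = FALSE],
           c("age", "sex", "batch")),
         cluster = reorder(cluster)[[3]],
         sex = factor(reorder(sex)[[3]], levels = c("F", "M")),
         sample_ids = ids, grm_full = compute_grm(genotypes),
         cohort = NULL)
  }
}

#' Run the full variance-decomposition study
#'
#' For every cluster, sex stratum and trauma category: computes the
#' cluster GRM, trauma PCs and the environmental relationship matrix
#' (optionally PC1-only and/or BLUP-precorrected), the Hadamard
#' interaction kernel, fits the requested models by AI-REML with the
#' standard covariates (age, sex where applicable, batch/array and the
#' first `n_grm_pcs` full-sample GRM principal components), runs the
#' nested likelihood-ratio tests (model 3 vs 1, 3 vs 2, 4 vs 3),
#' converts binary-outcome proportions to the liability scale, and pools
#' each component's per-cluster estimates by inverse-variance
#' meta-analysis. Deterministic given the config seed.
#'
#' Cell failures (e.g. REML non-convergence) are recorded in `failures`
#' and the remaining grid continues.
#'
#' @param config A [study_config()].
#' @return Object of class `study_result`: `components` (long table of
#'   per-cell component estimates), `lrt` (per-cell LRT table), `meta`
#'   (pooled table per stratum x category x model x component),
#'   `failures`, `manifest`, `inputs` (the assembled inputs, for
#'   downstream sensitivity analysis).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  inputs <- load_study_inputs(config)
  binary <- all(inputs$phenotype %in% c(0, 1))
  if (binary) {
    need <- setdiff(config$strata, names(config$prevalence_map %||% list()))
    if (length(need))
      stop("binary outcome: prevalence_map must cover strata ",
           paste(need, collapse = ", "), call. = FALSE)
  }
  gpcs <- grm_pcs(inputs$grm_full, k = min(config$n_grm_pcs,
                                           length(inputs$sample_ids) - 1L))
  clusters <- sort(unique(inputs$cluster))
  comp_rows <- list(); lrt_rows <- list(); fail_rows <- list()
  log_lines <- character(0)

  for (cl in clusters) {
    in_cl <- inputs$cluster == cl
    for (stratum in config$strata) {
      in_str <- in_cl & (if (stratum == "joint") TRUE
                         else inputs$sex == stratum)
      idx <- which(in_str)
      sub_geno <- list(counts = inputs$genotypes$counts[idx, , drop = FALSE],
                       sample_ids = inputs$sample_ids[idx],
                       snp_ids = inputs$genotypes$snp_ids,
                       allele_freqs = NULL,
                       sib_pairs = matrix(integer(0), 0, 2))
      class(sub_geno) <- "genotypes"
      G <- tryCatch(compute_grm(sub_geno), error = function(e) e)
      if (inherits(G, "error")) {
        fail_rows[[length(fail_rows) + 1]] <- data.frame(
          cluster = cl, stratum = stratum, category = NA, model = NA,
          stage = "grm", message = conditionMessage(G))
        next
      }
      if (config$unrelated_only) {
        keep_ids <- filter_unrelated(G, config$unrelated_threshold)
        sel <- match(keep_ids, sub_geno$sample_ids)
        idx <- idx[sel]
        sub_geno$counts <- sub_geno$counts[sel, , drop = FALSE]
        sub_geno$sample_ids <- keep_ids
        G <- compute_grm(sub_geno)
      }
      covar <- data.frame(age = inputs$covariates$age[idx],
                          batch = inputs$covariates$batch[idx],
                          gpcs$scores[idx, , drop = FALSE])
      if (stratum == "joint") covar$sex <- inputs$covariates$sex[idx]
      y <- inputs$phenotype[idx]
      prev <- if (binary) config$prevalence_map[[stratum]] else NULL

      for (category in config$trauma_categories) {
        cell <- sprintf("cluster %s / %s / %s", cl, stratum, category)
        res <- tryCatch({
          k <- if (config$pc_mode == "pc1_only") 1L else NULL
          pcs <- compute_trauma_pcs(inputs$items[idx, , drop = FALSE],
                                    category_labels = inputs$item_categories,
                                    category = category, k = k)
          if (config$precorrect)
            pcs <- precorrect_pcs(pcs, G, covariates = covar)
          E <- compute_erm(pcs)
          fit_cell_models(y, covar, G, E, config$models, prev, cl,
                          stratum, category)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          fail_rows[[length(fail_rows) + 1]] <- data.frame(
            cluster = cl, stratum = stratum, category = category,
            model = NA, stage = "fit", message = conditionMessage(res))
          next
        }
        comp_rows <- c(comp_rows, res$components)
        lrt_rows <- c(lrt_rows, res$lrt)
        log_lines <- c(log_lines, res$log)
      }
    }
  }

  components <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL
  lrt_tab <- if (length(lrt_rows)) do.call(rbind, lrt_rows) else NULL
  failures <- if (length(fail_rows)) do.call(rbind, fail_rows) else NULL

  meta_tab <- NULL
  if (!is.null(components) && length(clusters) >= 2) {
    key <- interaction(components$stratum, components$category,
                       components$model, components$component, drop = TRUE)
    meta_list <- lapply(split(components, key), function(g) {
      ok <- is.finite(g$proportion) & is.finite(g$prop_se) & g$prop_se > 0
      if (sum(ok) < 2) return(NULL)
      m <- meta_pool(g$proportion[ok], g$prop_se[ok],
                     method = config$meta_method)
      data.frame(stratum = g$stratum[1], category = g$category[1],
                 model = g$model[1], component = g$component[1],
                 estimate = m$estimate, se = m$se, Q = m$Q,
                 tau2 = m$tau2, I2 = m$I2, k_clusters = m$k_studies,
                 method = config$meta_method)
    })
    meta_tab <- do.call(rbind, meta_list)
    if (!is.null(meta_tab)) rownames(meta_tab) <- NULL
  }

  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   n_individuals = length(inputs$sample_ids),
                   n_snps = ncol(inputs$genotypes$counts),
                   clusters = clusters,
                   binary_outcome = binary,
                   meta_method = config$meta_method,
                   package_version = as.character(
                     utils::packageVersion("gxevc")),
                   timestamp = NA)  # kept NA so outputs are byte-stable

  out <- structure(list(components = components, lrt = lrt_tab,
                        meta = meta_tab, failures = failures,
                        manifest = manifest, log = log_lines,
                        inputs = inputs, config = config),
                   class = "study_result")
  if (!is.null(config$out_dir)) write_study_result(out, config$out_dir)
  out
}

# Fit the requested models in one grid cell, plus LRTs and liability
# conversion. Model 4 is warm-started from model 3.
fit_cell_models <- function(y, covar, G, E, models, prevalence, cl,
                            stratum, category) {
  fits <- list()
  comp <- list(); lrts <- list(); logs <- character(0)
  need <- sort(unique(c(models,
                        if (4 %in% models) 3L,
                        if (3 %in% models) c(1L, 2L))))
  for (mod in need) {
    start <- NULL
    if (mod == 4L && !is.null(fits[["3"]])) {
      s3 <- fits[["3"]]$sigma2
      start <- c(s3[["G"]], s3[["E"]], s3[["residual"]] / 2,
                 s3[["residual"]] / 2)
    }
    fits[[as.character(mod)]] <- fit_mlm(y, covar, G = G, E = E,
                                         model = mod, start = start)
    f <- fits[[as.character(mod)]]
    logs <- c(logs, sprintf(
      "cluster=%s stratum=%s category=%s model=%d iter=%d converged=%s logL=%.4f",
      cl, stratum, category, mod, f$n_iter, f$converged, f$loglik))
    if (mod %in% models) {
      vp <- variance_proportions(f, prevalence = prevalence)
      vp <- data.frame(cluster = cl, stratum = stratum,
                       category = category, model = mod, vp)
      comp[[length(comp) + 1]] <- vp
    }
  }
  pair_test <- function(full, red, label) {
    if (!is.null(fits[[full]]) && !is.null(fits[[red]])) {
      t <- lrt(fits[[full]], fits[[red]])
      data.frame(cluster = cl, stratum = stratum, category = category,
                 comparison = label, statistic = t$statistic, df = t$df,
                 p_value = t$p_value)
    }
  }
  lrts <- Filter(Negate(is.null), list(
    pair_test("3", "1", "3_vs_1"),
    pair_test("3", "2", "3_vs_2"),
    pair_test("4", "3", "4_vs_3")))
  list(components = comp, lrt = lrts, log = logs)
}

config_hash <- function(config) {
  config$out_dir <- NULL
  key <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  sprintf("%08x", child_seed(0L, key))
}

write_study_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df))
      utils::write.table(format(df, digits = 10), file.path(out_dir, name),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(result$components, "components.tsv")
  wr(result$lrt, "lrt.tsv")
  wr(result$meta, "meta.tsv")
  wr(result$failures, "failures.tsv")
  writeLines(result$log, file.path(out_dir, "fit_log.txt"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Variance-decomposition study\n")
  cat(sprintf("  %d component rows, %d LRT rows, %d failures\n",
              NROW(x$components), NROW(x$lrt), NROW(x$failures)))
  if (!is.null(x$meta)) {
    cat("  Meta-analyzed model-4 proportions:\n")
    m4 <- x$meta[x$meta$model == 4, ]
    for (i in seq_len(nrow(m4)))
      cat(sprintf("    %-8s %-10s %-5s %.4f (SE %.4f)\n", m4$stratum[i],
                  m4$category[i], m4$component[i], m4$estimate[i],
                  m4$se[i]))
  }
  invisible(x)
}

#' Prevalence sensitivity of liability-scale estimates
#'
#' Recomputes the liability conversion of every binary-outcome component
#' proportion under each alternative prevalence, and reports the LRT
#' significance pattern alongside. The conversion is a deterministic
#' rescaling of the observed-scale fit, so the likelihoods and tests are
#' unchanged across prevalences — only the liability-scale magnitudes
#' move.
#'
#' @param result A [run_study()] result with a binary outcome.
#' @param prevalences Non-empty numeric vector of prevalences in (0, 1).
#' @param alpha Significance level for the reported LRT pattern.
#' @return List: `liability` (long table: one row per component row x
#'   prevalence) and `significance` (LRT comparisons with
#'   `significant = p < alpha`, identical across prevalences).
#' @export
sensitivity_prevalence <- function(result, prevalences, alpha = 0.05) {
  stopifnot(inherits(result, "study_result"))
  if (!length(prevalences)) stop("empty prevalence list", call. = FALSE)
  for (K in prevalences)
    check_proportion(K, "prevalence", open_left = TRUE, open_right = TRUE)
  comp <- result$components
  if (is.null(comp)) stop("no component estimates in result", call. = FALSE)
  rows <- lapply(prevalences, function(K) {
    fac <- observed_to_liability(1, K)
    is_res <- comp$component == "residual"
    data.frame(comp[c("cluster", "stratum", "category", "model",
                      "component", "proportion", "prop_se")],
               prevalence = K,
               liability = ifelse(is_res, NA_real_, comp$proportion * fac),
               liability_se = ifelse(is_res, NA_real_,
                                     comp$prop_se * fac))
  })
  sig <- NULL
  if (!is.null(result$lrt)) {
    sig <- result$lrt
    sig$significant <- sig$p_value < alpha
  }
  list(liability = do.call(rbind, rows), significance = sig)
}
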