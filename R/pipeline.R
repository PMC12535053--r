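#' Default pipeline run configuration
#'
#' A run configuration bundles every stage setting plus one master seed
#' from which each stage derives its own named substream (see
#' [derive_seed()]), so inserting or re-running a stage never reshuffles
#' the randomness of the others.
#'
#' @param preset scenario preset name (see [scenario_preset()]), or give
#'   `spec` directly.
#' @param spec optional `scenario_spec` overriding `preset`.
#' @param stages stages to run, in order, among `"simulate"`,
#'   `"transpose"`, `"discover"`, `"benefit"`, `"match"`.
#' @param seed master seed.
#' @param outdir output directory for stage artifacts.
#' @param transpose_method `"LR"`, `"BN"`, or `"both"`.
#' @param clip membership-probability clipping bounds.
#' @param train_fraction training fraction for the 70/30 split.
#' @param t_star landmark time for the benefit stage (years).
#' @param t_star_external landmark time for the matched external cohort.
#' @param B bootstrap resamples for ARR confidence intervals.
#' @param with_replacement matching with replacement flag.
#' @param caliper optional matching caliper (logit-PS SD units).
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = "paper_like", spec = NULL,
                       stages = c("simulate", "transpose", "discover",
                                  "benefit", "match"),
                       seed = 1L, outdir = tempfile("survtransport_run_"),
                       transpose_method = "both", clip = c(0.005, 0.995),
                       train_fraction = 0.70, t_star = 3.6,
                       t_star_external = 2.1, B = 1000,
                       with_replacement = TRUE, caliper = NULL) {
  structure(list(preset = preset, spec = spec, stages = stages, seed = seed,
                 outdir = outdir, transpose_method = transpose_method,
                 clip = clip, train_fraction = train_fraction,
                 t_star = t_star, t_star_external = t_star_external, B = B,
                 with_replacement = with_replacement, caliper = caliper),
            class = "run_config")
}

pipeline_log <- function(state, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(line, "\n", sep = "", file = state$logfile, append = TRUE)
}

write_artifact <- function(state, df, name) {
  path <- file.path(state$outdir, name)
  utils::write.csv(df, path, row.names = FALSE)
  pipeline_log(state, "wrote ", name, " md5=", unname(tools::md5sum(path)))
  path
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order — simulate (synthetic cohorts),
#' transpose (inverse-odds-weighted hazard ratios against the target
#' population), discover (70/30 split, elastic-net modifier screening,
#' subgroup tree, held-out subgroup effects), benefit (per-subgroup
#' G-computation risks, ARR/NNT with bootstrap CIs, interaction tests),
#' match (propensity matching of the external new-user cohort, balance,
#' comparator Cox, external benefit report) — writing per-stage CSV
#' artifacts, a run log, and a plain-text summary into `config$outdir`.
#' Any stage error aborts with the stage name; artifacts of completed
#' stages persist.
#'
#' @param config a `run_config`.
#' @return list of class `pipeline_result` with the in-memory stage
#'   outputs and `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- list(outdir = config$outdir,
                logfile = file.path(config$outdir, "run_log.txt"))
  cat("", file = state$logfile)
  pipeline_log(state, "master seed = ", config$seed,
               "; stages = ", paste(config$stages, collapse = ","))
  res <- list(outdir = config$outdir, config = config)
  run_stage <- function(name, fun) {
    pipeline_log(state, "stage ", name, " start")
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  bundle <- NULL
  if ("simulate" %in% config$stages) {
    bundle <- run_stage("simulate", function() {
      spec <- config$spec %||% scenario_preset(config$preset)
      b <- generate_scenario(spec, seed = derive_seed(config$seed, "simulate"))
      for (nm in names(b$trials))
        write_cohort(b$trials[[nm]],
                     file.path(config$outdir, paste0("cohort_", nm, ".csv")))
      if (!is.null(b$target))
        write_cohort(b$target, file.path(config$outdir, "cohort_target.csv"))
      if (!is.null(b$rw))
        write_cohort(b$rw, file.path(config$outdir, "cohort_rw.csv"))
      writeLines(c(paste("preset:", config$preset %||% "(custom spec)"),
                   paste("master_seed:", config$seed),
                   paste("sizes:", paste(names(spec$n), unlist(spec$n),
                                         sep = "=", collapse = " "))),
                 file.path(config$outdir, "provenance.txt"))
      b
    })
    res$bundle <- bundle
  }
  if (is.null(bundle) &&
      any(c("transpose", "discover", "benefit", "match") %in% config$stages))
    stop("stages beyond 'simulate' require the simulate stage in this run")
  if ("transpose" %in% config$stages) {
    res$transposition <- run_stage("transpose", function() {
      methods <- if (config$transpose_method == "both") c("LR", "BN")
        else config$transpose_method
      rows <- list()
      for (nm in names(bundle$trials)) for (m in methods) {
        tr <- transpose(bundle$trials[[nm]], bundle$target, method = m,
                        clip = config$clip,
                        settings = list(seed = derive_seed(config$seed,
                                                           paste0("bn/", nm))))
        rows[[paste(nm, m)]] <- data.frame(
          trial = nm, method = m,
          hr_unweighted = tr$unweighted$hr,
          lo_unweighted = tr$unweighted$ci_lower,
          hi_unweighted = tr$unweighted$ci_upper,
          hr_transposed = tr$transposed$hr,
          lo_transposed = tr$transposed$ci_lower,
          hi_transposed = tr$transposed$ci_upper,
          n = tr$unweighted$n, events = tr$unweighted$events,
          ess = tr$transposed$ess,
          interaction_p = tr$interaction$p_value,
          stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      rownames(tab) <- NULL
      write_artifact(state, tab, "transposition.csv")
      tab
    })
  }
  disc <- NULL
  if ("discover" %in% config$stages) {
    disc <- run_stage("discover", function() {
      pooled <- pooled_trials(bundle)
      sp <- split_train_test(pooled, split_protocol(
        config$train_fraction, seed = derive_seed(config$seed, "split")))
      risk <- fit_control_risk_model(sp$train)
      ranking <- elastic_net_interaction_filter(
        sp$train, seed = derive_seed(config$seed, "elastic"))
      tree <- derive_subgroup_tree(sp$train, ranking)
      write_artifact(state, ranking$ranking, "modifier_ranking.csv")
      writeLines(utils::capture.output(print(tree)),
                 file.path(config$outdir, "subgroup_tree.txt"))
      eff <- rbind(cbind(set = "train",
                         evaluate_subgroups(sp$train, tree)),
                   cbind(set = "test", evaluate_subgroups(sp$test, tree)))
      write_artifact(state, eff, "subgroup_effects.csv")
      shares <- NULL
      if (!is.null(bundle$target)) {
        both <- rbind(subgroup_proportions(assign_subgroups(pooled, tree)),
                      subgroup_proportions(assign_subgroups(bundle$target,
                                                            tree)))
        shares <- both
        write_artifact(state, both, "subgroup_shares.csv")
      }
      list(split = sp, risk = risk, ranking = ranking, tree = tree,
           effects = eff, shares = shares)
    })
    res$discovery <- disc
  }
  if ("benefit" %in% config$stages) {
    res$benefit <- run_stage("benefit", function() {
      pooled <- pooled_trials(bundle)
      rep <- subgroup_benefit_report(
        pooled, disc$tree,
        plan = bootstrap_plan(config$B, seed = derive_seed(config$seed,
                                                           "boot")),
        t_star = config$t_star, sensitivity = TRUE)
      write_artifact(state, rep$table, "benefit.csv")
      trace <- do.call(rbind, lapply(rep$benefits, function(bn)
        data.frame(subgroup = bn$subgroup, resample = seq_along(bn$boot),
                   arr = bn$boot)))
      write_artifact(state, trace, "benefit_bootstrap_trace.csv")
      foot <- data.frame(
        statistic = c("relative_interaction_p", "gail_simon_qualitative_p",
                      "gail_simon_quantitative_p"),
        value = c(rep$relative_interaction$p_value %||% NA_real_,
                  rep$gail_simon$p_qualitative %||% NA_real_,
                  rep$gail_simon$p_quantitative %||% NA_real_))
      write_artifact(state, foot, "benefit_interactions.csv")
      rep
    })
  }
  if ("match" %in% config$stages && !is.null(bundle$rw)) {
    res$matching <- run_stage("match", function() {
      ps <- estimate_propensity(bundle$rw)
      mt <- nn_match(ps, bundle$rw,
                     with_replacement = config$with_replacement,
                     caliper = config$caliper)
      bal <- balance_report(bundle$rw, mt)
      write_artifact(state, mt$pairs, "match_pairs.csv")
      write_artifact(state, bal$table, "match_balance.csv")
      eff <- comparator_cox(bundle$rw, mt, tree = disc$tree)
      write_artifact(state, eff, "external_effects.csv")
      ext_benefit <- NULL
      if (!is.null(disc$tree)) {
        md <- matched_analysis_set(bundle$rw, mt)
        md <- md[rep(seq_len(nrow(md)), md$.fw), , drop = FALSE]
        md$subject_id <- paste0(md$subject_id, "_", seq_len(nrow(md)))
        mc <- cohort_table(md[, setdiff(names(md), ".fw")],
                           schema = cohort_schema(bundle$rw))
        ext_benefit <- subgroup_benefit_report(
          mc, disc$tree,
          plan = bootstrap_plan(config$B,
                                seed = derive_seed(config$seed, "boot_ext")),
          t_star = config$t_star_external)
        write_artifact(state, ext_benefit$table, "external_benefit.csv")
      }
      list(ps = ps, match = mt, balance = bal, effects = eff,
           benefit = ext_benefit)
    })
  }
  emit_report(config$outdir)
  class(res) <- "pipeline_result"
  res
}

read_artifact <- function(outdir, name) {
  path <- file.path(outdir, name)
  if (!file.exists(path)) return(NULL)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Regenerate the plain-text summary from saved stage artifacts
#'
#' Reads whatever stage CSVs exist under `outdir` and writes
#' `summary.txt`; sections whose artifacts are absent are marked
#' "not run". Idempotent: every number in the summary is read back from a
#' CSV cell.
#'
#' @param outdir directory holding pipeline artifacts.
#' @return path of the summary file, invisibly.
#' @export
emit_report <- function(outdir) {
  out <- c("== survtransport pipeline summary ==", "")
  sec <- function(title, df, fmt) {
    if (is.null(df)) return(c(paste0("-- ", title, ": not run --"), ""))
    c(paste0("-- ", title, " --"), fmt(df), "")
  }
  out <- c(out, sec("Transposition", read_artifact(outdir, "transposition.csv"),
    function(df) sprintf(
      "%s [%s] unweighted HR %.3f (%.3f-%.3f); transposed HR %.3f (%.3f-%.3f); ESS %.0f/%d; weight x treatment p=%.3f",
      df$trial, df$method, df$hr_unweighted, df$lo_unweighted,
      df$hi_unweighted, df$hr_transposed, df$lo_transposed, df$hi_transposed,
      df$ess, df$n, df$interaction_p)))
  tree_path <- file.path(outdir, "subgroup_tree.txt")
  out <- c(out,
           if (file.exists(tree_path))
             c("-- Subgroup tree --", readLines(tree_path), "")
           else c("-- Subgroup tree: not run --", ""))
  out <- c(out, sec("Subgroup effects",
                    read_artifact(outdir, "subgroup_effects.csv"),
    function(df) sprintf("%s set, group %s: HR %.3f (%.3f-%.3f), n=%d, events=%d%s",
                         df$set, df$subgroup, df$hr, df$ci_lower, df$ci_upper,
                         df$n, df$events,
                         ifelse(df$flagged, " [flagged: zero events in an arm]",
                                ""))))
  out <- c(out, sec("Subgroup shares",
                    read_artifact(outdir, "subgroup_shares.csv"),
    function(df) sprintf("%s: group %s share %.3f", df$source, df$subgroup,
                         df$proportion)))
  out <- c(out, sec("Clinical benefit", read_artifact(outdir, "benefit.csv"),
    function(df) sprintf(
      "group %s: HR %.3f (%.3f-%.3f); risks C/T %.3f/%.3f; ARR %.3f (%.3f-%.3f); NNT %s",
      df$subgroup, df$hr, df$ci_lower, df$ci_upper, df$risk_control,
      df$risk_treated, df$arr, df$arr_lower, df$arr_upper,
      ifelse(df$nnt_defined, as.character(df$nnt),
             paste0(df$nnt, " (not defined: CI crosses 0)")))))
  out <- c(out, sec("Interaction tests",
                    read_artifact(outdir, "benefit_interactions.csv"),
    function(df) sprintf("%s = %.4f", df$statistic, df$value)))
  out <- c(out, sec("External validation",
                    read_artifact(outdir, "external_effects.csv"),
    function(df) sprintf("%s: HR %.3f (%.3f-%.3f), n=%d%s",
                         df$subgroup, df$hr, df$ci_lower, df$ci_upper, df$n,
                         ifelse(df$adjusted_for == "", "",
                                paste0(" [adjusted: ", df$adjusted_for, "]")))))
  path <- file.path(outdir, "summary.txt")
  writeLines(out, path)
  invisible(path)
}
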