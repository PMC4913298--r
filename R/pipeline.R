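#' Declarative experiment configuration
#'
#' One object drives a full seeded run: chain topology and size(s), trial
#' generator settings, SVM penalty, and which analyses to produce. Two
#' profiles set scale defaults: `"desk"` (k = 50, M = 20, N = 60; minutes on
#' one CPU) and `"paper"` (k = 500, M = 50, N = 100; the reference
#' experimental scale — M and N are free choices, so this profile is
#' nominal, not exact).
#'
#' @param topology `"line"`, `"complete"`, or `"custom"`.
#' @param n chain size(s); a vector runs one sub-experiment per value.
#' @param profile `"desk"` or `"paper"`; sets `N`, `M`, `k` unless given.
#' @param N,M,k,p_switch,seed,mode see [trial_config()].
#' @param svm_C SVM penalty.
#' @param analyses subset of `c("accuracy", "mi", "spectra",
#'   "average_position")`.
#' @param custom_transition transition matrix, required when
#'   `topology = "custom"`.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(topology = "line", n = 5, profile = c("desk", "paper"),
                              N = NULL, M = NULL, k = NULL, p_switch = 0.001,
                              svm_C = 1, seed = 1L, mode = "reversed",
                              analyses = c("accuracy", "mi", "spectra",
                                           "average_position"),
                              custom_transition = NULL) {
  profile <- match.arg(profile)
  if (!topology %in% c("line", "complete", "custom")) {
    stop("`topology` must be line, complete or custom", call. = FALSE)
  }
  if (topology == "custom" && is.null(custom_transition)) {
    stop("custom topology needs `custom_transition`", call. = FALSE)
  }
  defaults <- if (profile == "desk") list(N = 60L, M = 20L, k = 50L)
              else list(N = 100L, M = 50L, k = 500L)
  bad <- setdiff(analyses, c("accuracy", "mi", "spectra", "average_position"))
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(
    list(topology = topology, n = as.integer(n), profile = profile,
         N = as.integer(N %||% defaults$N), M = as.integer(M %||% defaults$M),
         k = as.integer(k %||% defaults$k), p_switch = p_switch,
         svm_C = svm_C, seed = as.integer(seed), mode = mode,
         analyses = analyses, custom_transition = custom_transition),
    class = "experiment_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write experiment configurations as JSON
#'
#' Round-trips exactly: a config written to its sidecar and reloaded
#' reproduces the identical run.
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` returns the config.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  doc <- unclass(config)
  if (!is.null(doc$custom_transition)) {
    doc$custom_transition <- apply(unname(doc$custom_transition), 1, c,
                                   simplify = FALSE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ct <- doc$custom_transition
  if (is.null(ct) || length(ct) == 0L) {
    ct <- NULL
  } else {
    if (is.list(ct)) ct <- do.call(rbind, ct)
    ct <- as.matrix(ct)
  }
  experiment_config(topology = doc$topology, n = doc$n, profile = doc$profile,
                    N = doc$N, M = doc$M, k = doc$k, p_switch = doc$p_switch,
                    svm_C = doc$svm_C, seed = doc$seed, mode = doc$mode,
                    analyses = doc$analyses, custom_transition = ct)
}

build_chain <- function(config, n) {
  switch(config$topology,
         line = line_chain(n),
         complete = complete_chain(n),
         custom = markov_chain(config$custom_transition, topology = "custom"))
}

log_line <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[vetowalk %s] ", fmt),
                               format(Sys.time(), "%H:%M:%S"), ...))
}

#' Run a full seeded experiment to disk
#'
#' For each chain size in the config: generates the trial set, writes it as
#' CSV with a JSON sidecar, and produces the requested analyses (accuracy
#' time course, exact MI time course, spectral summary, average-position
#' curve) as CSV/JSON tables in `out_dir`. Deterministic given the seed;
#' analytic outputs (MI, spectra) do not depend on the seed at all. On
#' failure, files created by the partial run are removed.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose emit per-stage log lines?
#' @return Invisibly, a named list of written file paths per chain size.
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("run_experiment failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  }
  result <- tryCatch({
    write_experiment_config(config, file.path(out_dir, "config.json"))
    written <- c(written, file.path(out_dir, "config.json"))
    bundles <- list()
    for (n in config$n) {
      tag <- sprintf("%s_n%d", config$topology, n)
      log_line(verbose, "start %s (seed=%d, k=%d, M=%d, N=%d)", tag,
               config$seed, config$k, config$M, config$N)
      chain <- build_chain(config, n)
      files <- character(0)
      t0 <- Sys.time()
      tcfg <- trial_config(chain, N = config$N, M = config$M, k = config$k,
                           p_switch = config$p_switch,
                           seed = config$seed + which(config$n == n) - 1L,
                           mode = config$mode)
      trials <- generate_trials(tcfg)
      f <- file.path(out_dir, sprintf("trials_%s.csv", tag))
      write_trials_csv(trials, f)
      files <- c(files, f, paste0(f, ".json"))
      log_line(verbose, "%s: trials generated (%.2fs)", tag,
               as.numeric(Sys.time() - t0, units = "secs"))
      if ("accuracy" %in% config$analyses) {
        t0 <- Sys.time()
        acc <- accuracy_timecourse(trials, C = config$svm_C)
        f <- file.path(out_dir, sprintf("accuracy_%s.csv", tag))
        write_accuracy_csv(acc, f)
        files <- c(files, f, sub("\\.csv$", "_grand.csv", f))
        log_line(verbose, "%s: accuracy time course done (%.2fs)", tag,
                 as.numeric(Sys.time() - t0, units = "secs"))
      }
      if ("mi" %in% config$analyses) {
        mi <- mi_timecourse(chain, config$N)
        f <- file.path(out_dir, sprintf("mi_%s.csv", tag))
        write_mi_csv(mi, f)
        files <- c(files, f)
        log_line(verbose, "%s: MI time course done", tag)
      }
      if ("spectra" %in% config$analyses) {
        sp <- spectral_summary(chain)
        f <- file.path(out_dir, sprintf("spectra_%s.json", tag))
        jsonlite::write_json(
          list(n = n, topology = config$topology,
               eigenvalues = Mod(sp$eigenvalues), timescales = sp$timescales,
               relaxation_time = sp$relaxation_time, defective = sp$defective),
          f, auto_unbox = TRUE, digits = NA)
        files <- c(files, f)
        log_line(verbose, "%s: spectra done (tau1 = %.4g)", tag,
                 sp$relaxation_time)
      }
      if ("average_position" %in% config$analyses) {
        avg <- average_position_curve(trials)
        f <- file.path(out_dir, sprintf("avgpos_%s.csv", tag))
        write.csv(avg, f, row.names = FALSE, quote = FALSE)
        files <- c(files, f)
        log_line(verbose, "%s: average-position curve done", tag)
      }
      written <- c(written, files)
      bundles[[tag]] <- files
    }
    bundles
  }, error = on_fail)
  invisible(result)
}

#' Qualitative figure checks on a result bundle
#'
#' Re-reads the tables produced by [run_experiment()] and evaluates the
#' study's qualitative claims: grand-mean accuracy 100 at `t = 0` (line
#' chains), the complete-graph 50 +/- 2 plateau at `t <= -1`, the SVM
#' grand mean not exceeding the analytic Bayes bound by more than `3`
#' Monte-Carlo standard errors, time-locked MI equal to 1 bit at `t = 0` with
#' unconstrained MI identically zero, MI decay ordering by chain size, and
#' relaxation-time ordering `tau_1(n)` increasing for lines / zero for
#' complete graphs. Missing bundle components mark their checks `"skipped"`.
#'
#' @param out_dir directory written by [run_experiment()].
#' @return `data.frame` with columns `check`, `status` (`"pass"`, `"fail"`,
#'   `"skipped"`), `detail`; attribute `ok` is TRUE only if all checks pass.
#' @export
compare_figures <- function(out_dir) {
  cfg_path <- file.path(out_dir, "config.json")
  if (!file.exists(cfg_path)) stop("no config.json in ", out_dir, call. = FALSE)
  config <- read_experiment_config(cfg_path)
  rows <- list()
  add <- function(check, status, detail = "") {
    rows[[length(rows) + 1]] <<- data.frame(check = check, status = status,
                                            detail = detail)
  }
  taus <- c()
  for (n in config$n) {
    tag <- sprintf("%s_n%d", config$topology, n)
    g_path <- file.path(out_dir, sprintf("accuracy_%s_grand.csv", tag))
    if ("accuracy" %in% config$analyses) {
      if (!file.exists(g_path)) {
        add(sprintf("accuracy[%s]", tag), "skipped", "grand-mean CSV missing")
      } else {
        g <- read.csv(g_path)
        a0 <- g$accuracy[g$t == 0]
        if (config$topology %in% c("line", "complete")) {
          add(sprintf("accuracy(t=0)=100 [%s]", tag),
              if (abs(a0 - 100) < 1e-9) "pass" else "fail",
              sprintf("a(0) = %.2f", a0))
        }
        pre <- g$accuracy[g$t <= -1]
        if (config$topology == "complete") {
          add(sprintf("plateau 50+/-2 for t<=-1 [%s]", tag),
              if (all(abs(pre - 50) <= 2)) "pass" else "fail",
              sprintf("range [%.2f, %.2f]", min(pre), max(pre)))
        }
        # Bayes bound with 3 MC standard errors from the per-participant sheet
        p_path <- file.path(out_dir, sprintf("accuracy_%s.csv", tag))
        if (file.exists(p_path)) {
          per <- read.csv(p_path)
          chain <- build_chain(config, n)
          bayes <- bayes_accuracy_curve(chain, config$N)
          ok <- TRUE
          for (tt in bayes$times) {
            vals <- per$accuracy[per$t == tt]
            se <- stats::sd(vals) / sqrt(length(vals))
            if (mean(vals) > bayes$percent[bayes$times == tt] + 3 * se + 1e-9) {
              ok <- FALSE; break
            }
          }
          add(sprintf("grand mean <= Bayes + 3 SE [%s]", tag),
              if (ok) "pass" else "fail")
        }
      }
    }
    mi_path <- file.path(out_dir, sprintf("mi_%s.csv", tag))
    if ("mi" %in% config$analyses) {
      if (!file.exists(mi_path)) {
        add(sprintf("mi[%s]", tag), "skipped", "MI CSV missing")
      } else {
        mi <- read.csv(mi_path)
        ok <- abs(mi$I0_bits[mi$t == 0] - 1) < 1e-9 && all(mi$I_bits == 0)
        add(sprintf("I0(0)=1, I=0 [%s]", tag), if (ok) "pass" else "fail")
      }
    }
    sp_path <- file.path(out_dir, sprintf("spectra_%s.json", tag))
    if ("spectra" %in% config$analyses) {
      if (!file.exists(sp_path)) {
        add(sprintf("spectra[%s]", tag), "skipped", "spectra JSON missing")
      } else {
        sp <- jsonlite::read_json(sp_path, simplifyVector = TRUE)
        taus[as.character(n)] <- sp$relaxation_time
      }
    }
  }
  if (length(taus) > 1 && config$topology == "line") {
    ord <- all(diff(taus[order(as.integer(names(taus)))]) > 0)
    add("tau1 increases with n (line)", if (ord) "pass" else "fail",
        paste(sprintf("tau1(%s)=%.3g", names(taus), taus), collapse = ", "))
  }
  if (length(taus) >= 1 && config$topology == "complete") {
    add("tau1 = 0 (complete)", if (all(taus < 1e-9)) "pass" else "fail")
  }
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$status == "pass")
  out
}
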