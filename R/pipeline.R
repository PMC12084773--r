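# End-to-end orchestration: descriptives -> wave-wise GGMs + expected
# influence -> wave-pair network comparison -> cross-lagged panel networks
# + directed centralities -> bootstrap/stability suite -> one report.

#' Cronbach's alpha of a set of item columns
#'
#' \code{alpha = k/(k-1) * (1 - sum(item variances)/variance(total))}.
#' @param x participants x items matrix.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2) return(NA_real_)
  vt <- var(rowSums(x))
  if (vt == 0) {
    warning("total score has zero variance; alpha undefined")
    return(NA_real_)
  }
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / vt)
}

#' Welch two-sample t test on total scores (attrition check)
#'
#' Descriptive convenience comparing completers and dropouts on a total
#' score.
#' @param completers,dropouts numeric vectors of totals.
#' @export
attrition_test <- function(completers, dropouts) {
  t.test(completers, dropouts, var.equal = FALSE)
}

# Item columns per reporting scale.
scale_members <- function(scheme) {
  nd <- scheme$node_ids
  list(IAT = nd[scheme$construct == "IA"],
       depression = nd[scheme$construct == "depression"],
       anxiety = nd[scheme$construct == "anxiety"],
       stress = nd[scheme$construct == "stress"],
       DASS = nd[scheme$construct != "IA"])
}

#' Descriptive statistics of a panel dataset
#'
#' Per node per wave mean and SD, and per scale per wave the total-score
#' mean/SD and Cronbach's alpha over the scale's node columns.
#'
#' @param panel a complete \code{panel_dataset}.
#' @return list(nodes = data.frame(node, wave, mean, sd),
#'   scales = data.frame(scale, wave, total_mean, total_sd, alpha)).
#' @export
descriptives <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  scheme <- panel$scheme
  node_rows <- list(); scale_rows <- list()
  members <- scale_members(scheme)
  for (w in panel$waves) {
    m <- wave_matrix(panel, w)
    if (anyNA(m))
      stop("wave ", w, " contains missing values; apply complete_case_filter()",
           call. = FALSE)
    node_rows[[w]] <- data.frame(node = colnames(m), wave = w,
                                 mean = colMeans(m), sd = apply(m, 2, sd),
                                 stringsAsFactors = FALSE)
    scale_rows[[w]] <- do.call(rbind, lapply(names(members), function(sc) {
      cols <- m[, members[[sc]], drop = FALSE]
      tot <- rowSums(cols)
      a <- if (any(apply(cols, 2, sd) == 0)) {
        warning("constant node in scale ", sc, " at ", w, "; alpha skipped")
        NA_real_
      } else cronbach_alpha(cols)
      data.frame(scale = sc, wave = w, total_mean = mean(tot),
                 total_sd = sd(tot), alpha = a, stringsAsFactors = FALSE)
    }))
  }
  nodes <- do.call(rbind, node_rows); rownames(nodes) <- NULL
  scales <- do.call(rbind, scale_rows); rownames(scales) <- NULL
  list(nodes = nodes, scales = scales)
}

#' Configuration for a full panel network analysis
#'
#' @param seed integer seed (mandatory); every stochastic stage derives
#'   its own seed from it.
#' @param input optional path to a wide panel CSV (used when no panel is
#'   passed to \code{run_full_analysis}).
#' @param waves wave labels, in temporal order (3 waves).
#' @param ggm_nodes nodes for the cross-sectional networks: "IA" (the 6
#'   IA subscales, the default, matching a wave-wise IA symptom network),
#'   "all", or a character vector of node ids.
#' @param method,gamma correlation method and EBIC hyperparameter.
#' @param lambda_mode,lam,folds CLPN penalty options.
#' @param boot_iterations bootstrap draws (default 1200).
#' @param drop_grid,drop_iterations case-drop stability options.
#' @param nct_iterations,nct_paired network-comparison options.
#' @param run_bootstrap,run_stability toggle the robustness suite.
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @return An \code{analysis_config} list.
#' @export
analysis_config <- function(seed, input = NULL, waves = c("T1", "T2", "T3"),
                            ggm_nodes = "IA", method = "pearson", gamma = 0.5,
                            lambda_mode = "cv", lam = NULL, folds = 10L,
                            boot_iterations = 1200L,
                            drop_grid = seq(0.05, 0.75, by = 0.05),
                            drop_iterations = 50L,
                            nct_iterations = 1000L, nct_paired = TRUE,
                            run_bootstrap = TRUE, run_stability = TRUE,
                            output_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (length(waves) != 3) stop("exactly 3 waves are required", call. = FALSE)
  structure(list(seed = as.integer(seed), input = input, waves = waves,
                 ggm_nodes = ggm_nodes, method = method, gamma = gamma,
                 lambda_mode = lambda_mode, lam = lam, folds = folds,
                 boot_iterations = boot_iterations, drop_grid = drop_grid,
                 drop_iterations = drop_iterations,
                 nct_iterations = nct_iterations, nct_paired = nct_paired,
                 run_bootstrap = run_bootstrap, run_stability = run_stability,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Save or load an analysis configuration as JSON
#'
#' The round trip is lossless: \code{read_config(write_config(cfg, f))}
#' reproduces the configuration exactly.
#' @param config an \code{analysis_config}.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(analysis_config)
  args <- raw[intersect(names(raw), names(defaults))]
  if (!is.null(args$folds)) args$folds <- as.integer(args$folds)
  for (f in c("boot_iterations", "drop_iterations", "nct_iterations"))
    if (!is.null(args[[f]])) args[[f]] <- as.integer(args[[f]])
  do.call(analysis_config, args)
}

# Hash of the analysis-relevant parameters (paths excluded, so the same
# analysis written to different directories carries the same tag).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$input <- NULL
  cfg$output_dir <- NULL
  fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                           null = "null"))
}

resolve_ggm_nodes <- function(config, scheme) {
  if (identical(config$ggm_nodes, "IA"))
    scheme$node_ids[scheme$construct == "IA"]
  else if (identical(config$ggm_nodes, "all")) scheme$node_ids
  else {
    bad <- setdiff(config$ggm_nodes, scheme$node_ids)
    if (length(bad)) stop("unknown ggm_nodes: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    config$ggm_nodes
  }
}

#' Run the full panel network analysis
#'
#' Executes, in order: descriptives; one regularized partial-correlation
#' network per wave with EI1/EI2 centralities; paired network-comparison
#' tests for consecutive wave pairs; one CLPN per wave pair (T1->T2,
#' T2->T3, T1->T3) with IEI/OEI (cross-construct scope) and BEI1/BEI2
#' (outgoing); and the bootstrap + case-drop robustness suite. The run is
#' a deterministic function of (panel, config, seed). If a stage fails,
#' completed artifacts are still written (when \code{output_dir} is set)
#' and the error names the stage.
#'
#' @param config an \code{analysis_config}.
#' @param panel a complete \code{panel_dataset}; if NULL, loaded from
#'   \code{config$input}.
#' @return An \code{analysis_report} list; see the vignette for the
#'   layout.
#' @export
run_full_analysis <- function(config, panel = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(panel)) {
    if (is.null(config$input)) stop("no panel and no config$input", call. = FALSE)
    panel <- load_panel(config$input, waves = config$waves)
  }
  panel <- complete_case_filter(panel)
  if (!all(config$waves %in% panel$waves))
    stop("config waves not all present in the panel", call. = FALSE)
  scheme <- panel$scheme
  waves <- config$waves
  comm <- scheme_communities(scheme)
  ggm_nodes <- resolve_ggm_nodes(config, scheme)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, 32L))
  seed_i <- 0L
  next_seed <- function() { seed_i <<- seed_i + 1L; seeds[seed_i] }

  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("panelnet")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(config),
    n_participants = length(panel$participant_ids)))
  class(report) <- "analysis_report"

  current_stage <- "init"
  finish <- function() {
    if (!is.null(config$output_dir)) write_report(report, config$output_dir)
    report
  }
  run_stage <- function(name, expr) {
    current_stage <<- name
    tryCatch(expr, error = function(e) {
      if (!is.null(config$output_dir))
        try(write_report(report, config$output_dir), silent = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  run_stage("descriptives", {
    report$descriptives <- descriptives(panel)
  })

  run_stage("ggm", {
    ggms <- list(); ei <- list()
    for (w in waves) {
      x <- wave_matrix(panel, w, nodes = ggm_nodes)
      net <- estimate_ggm(x, method = config$method, gamma = config$gamma,
                          scheme = scheme)
      ggms[[w]] <- net
      ei[[w]] <- expected_influence(net)
    }
    report$ggm <- ggms
    report$expected_influence <- ei
  })

  run_stage("nct", {
    ncts <- list()
    for (k in 1:2) {
      wa <- waves[k]; wb <- waves[k + 1]
      ncts[[paste0(wa, "_vs_", wb)]] <- network_comparison_test(
        wave_matrix(panel, wa, nodes = ggm_nodes),
        wave_matrix(panel, wb, nodes = ggm_nodes),
        paired = config$nct_paired, iterations = config$nct_iterations,
        seed = next_seed(), gamma = config$gamma, method = config$method)
    }
    report$nct <- ncts
  })

  run_stage("clpn", {
    pairs <- list(c(1, 2), c(2, 3), c(1, 3))
    clpns <- list(); cents <- list(); counts <- integer(0)
    for (pr in pairs) {
      wf <- waves[pr[1]]; wt <- waves[pr[2]]
      key <- paste0(wf, "_to_", wt)
      net <- fit_clpn(panel, wf, wt, lambda_mode = config$lambda_mode,
                      lam = config$lam, folds = config$folds,
                      seed = next_seed())
      clpns[[key]] <- net
      io <- in_out_expected_influence(net, scope = "cross_construct")
      bei <- bridge_expected_influence(net, direction = "out")
      cents[[key]] <- merge(io, bei, by = "node", sort = FALSE)
      counts[key] <- count_nonzero_cross_lagged(net)
    }
    report$clpn <- clpns
    report$clpn_centrality <- cents
    report$nonzero_cross_lagged <- counts
  })

  if (config$run_bootstrap) run_stage("bootstrap", {
    boots <- list()
    for (w in waves) {
      boots[[paste0("ggm_", w)]] <- bootstrap_edges(
        wave_matrix(panel, w, nodes = ggm_nodes), "ggm",
        iterations = config$boot_iterations, seed = next_seed(),
        gamma = config$gamma, method = config$method)
    }
    pairs <- list(c(1, 2), c(2, 3), c(1, 3))
    for (pr in pairs) {
      wf <- waves[pr[1]]; wt <- waves[pr[2]]
      boots[[paste0("clpn_", wf, "_to_", wt)]] <- bootstrap_edges(
        list(from = wave_matrix(panel, wf), to = wave_matrix(panel, wt)),
        "clpn", iterations = config$boot_iterations, seed = next_seed(),
        lambda_mode = config$lambda_mode, lam = config$lam,
        folds = config$folds, communities = comm)
    }
    report$bootstrap <- boots
  })

  if (config$run_stability) run_stage("stability", {
    stab <- list()
    for (w in waves) {
      stab[[paste0("ggm_", w)]] <- case_drop_stability(
        wave_matrix(panel, w, nodes = ggm_nodes), "ggm",
        drop_grid = config$drop_grid, iterations = config$drop_iterations,
        seed = next_seed(), gamma = config$gamma, method = config$method)
    }
    pairs <- list(c(1, 2), c(2, 3), c(1, 3))
    for (pr in pairs) {
      wf <- waves[pr[1]]; wt <- waves[pr[2]]
      stab[[paste0("clpn_", wf, "_to_", wt)]] <- case_drop_stability(
        list(from = wave_matrix(panel, wf), to = wave_matrix(panel, wt)),
        "clpn", drop_grid = config$drop_grid,
        iterations = config$drop_iterations, seed = next_seed(),
        lambda_mode = config$lambda_mode, lam = config$lam,
        folds = config$folds, communities = comm)
    }
    report$stability <- stab
  })

  finish()
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Panel network analysis report\n")
  cat("  participants:", x$provenance$n_participants,
      " seed:", x$provenance$seed,
      " config:", x$provenance$config_hash, "\n")
  cat("  cross-sectional networks:", length(x$ggm),
      "| NCTs:", length(x$nct), "| CLPNs:", length(x$clpn), "\n")
  if (!is.null(x$nonzero_cross_lagged)) {
    cat("  nonzero cross-lagged edges:",
        paste(names(x$nonzero_cross_lagged), x$nonzero_cross_lagged,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an analysis report as CSV tables and JSON metadata
#'
#' Tables are written with fixed formatting, so identical reports produce
#' byte-identical files.
#' @param report an \code{analysis_report}.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(dir, name), row.names = FALSE)
  tag <- function(df) {
    df$seed <- rep(report$provenance$seed, length.out = nrow(df))
    df$config_hash <- rep(report$provenance$config_hash, length.out = nrow(df))
    df
  }
  if (!is.null(report$descriptives)) {
    w(tag(report$descriptives$nodes), "descriptives_nodes.csv")
    w(tag(report$descriptives$scales), "descriptives_scales.csv")
  }
  if (!is.null(report$ggm)) for (nm in names(report$ggm)) {
    net <- report$ggm[[nm]]
    w(tag(ggm_edge_list(net)), paste0("ggm_", nm, "_edges.csv"))
    ei <- report$expected_influence[[nm]]
    w(tag(as.data.frame(ei)), paste0("ggm_", nm, "_centrality.csv"))
    jsonlite::write_json(
      list(wave = nm, lambda = net$lambda_selected, ebic = net$ebic_value,
           gamma = net$gamma, n = net$n,
           global_strength = global_strength(net)),
      file.path(dir, paste0("ggm_", nm, "_meta.json")),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$nct)) {
    nct_df <- do.call(rbind, lapply(names(report$nct), function(nm) {
      x <- report$nct[[nm]]
      data.frame(comparison = nm, m_statistic = x$m_statistic,
                 p_invariance = x$p_invariance, s_statistic = x$s_statistic,
                 p_global = x$p_global, paired = x$paired,
                 iterations = x$iterations, stringsAsFactors = FALSE)
    }))
    w(tag(nct_df), "nct.csv")
  }
  if (!is.null(report$clpn)) for (nm in names(report$clpn)) {
    w(tag(clpn_edge_list(report$clpn[[nm]])), paste0("clpn_", nm, "_edges.csv"))
    w(tag(as.data.frame(report$clpn_centrality[[nm]])),
      paste0("clpn_", nm, "_centrality.csv"))
  }
  if (!is.null(report$nonzero_cross_lagged)) {
    w(tag(data.frame(network = names(report$nonzero_cross_lagged),
                     nonzero_cross_lagged = unname(report$nonzero_cross_lagged),
                     stringsAsFactors = FALSE)),
      "nonzero_cross_lagged.csv")
  }
  if (!is.null(report$bootstrap)) {
    ci_df <- do.call(rbind, lapply(names(report$bootstrap), function(nm) {
      b <- report$bootstrap[[nm]]
      data.frame(network = nm, edge = rownames(b$edge_ci),
                 observed = unname(b$observed$edges),
                 lower = b$edge_ci[, "lower"], upper = b$edge_ci[, "upper"],
                 stringsAsFactors = FALSE)
    }))
    rownames(ci_df) <- NULL
    w(tag(ci_df), "bootstrap_edge_ci.csv")
  }
  if (!is.null(report$stability)) {
    cs_df <- do.call(rbind, lapply(names(report$stability), function(nm) {
      s <- report$stability[[nm]]
      data.frame(network = nm, centrality_index = s$centrality_index,
                 cs_coefficient = s$cs_coefficient, stringsAsFactors = FALSE)
    }))
    w(tag(cs_df), "cs_coefficients.csv")
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
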