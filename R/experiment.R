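#' Experiment configuration
#'
#' Bundles the factorial design of the sensitivity study: tree sizes,
#' replicates per size, the trait-signal grid, the degradation levels, the
#' permutation count, the dual alpha levels of the bias screen and the
#' master seed. Defaults are the desk-scale configuration; the full-scale
#' design (1000 trees per set, sizes up to 1000 tips) is supported by
#' raising `n_trees` and `tree_sizes`.
#'
#' @param tree_sizes Tip counts of the tree sets.
#' @param n_trees Replicate trees per size.
#' @param lambda_grid Trait-signal levels simulated on every tree.
#' @param collapse_fractions Node-collapse fractions for the polytomic
#'   chronograms.
#' @param collapse_strategies Subset of `c("shallow", "all")`.
#' @param fix_fractions Fractions of fixed node ages for the
#'   pseudo-chronograms.
#' @param combined Logical: also build polytomic pseudo-chronograms (every
#'   fix fraction crossed with every shallow collapse fraction)?
#' @param indices Signal indices to run, subset of `c("K", "lambda")`.
#' @param n_perm Permutations for the K randomization test.
#' @param alpha_accept,alpha_reject Dual alpha levels of the bias screen;
#'   `alpha_reject < alpha_accept`.
#' @param birth_rate Speciation rate of the pure-birth simulator.
#' @param n_slices Time slices for constraint selection.
#' @param seed Master seed; every stochastic stage derives a child seed
#'   from it, so the whole experiment is reproducible.
#' @return An `experiment_config` list.
#' @examples
#' cfg <- experiment_config(tree_sizes = 50, n_trees = 2, n_perm = 99)
#' @export
experiment_config <- function(tree_sizes = c(50, 100, 200, 400, 1000),
                              n_trees = 100,
                              lambda_grid = seq(0.1, 0.9, by = 0.1),
                              collapse_fractions = c(0.2, 0.4, 0.6, 0.8),
                              collapse_strategies = c("shallow", "all"),
                              fix_fractions = c(0.05, 0.15, 0.25, 0.35),
                              combined = FALSE,
                              indices = c("K", "lambda"),
                              n_perm = 999,
                              alpha_accept = 0.05,
                              alpha_reject = 0.01,
                              birth_rate = 1,
                              n_slices = 5L,
                              seed = 1L) {
  stopifnot(
    all(tree_sizes >= 3), n_trees >= 1,
    all(lambda_grid >= 0 & lambda_grid <= 1),
    all(collapse_fractions >= 0 & collapse_fractions < 1),
    all(fix_fractions > 0 & fix_fractions <= 1),
    alpha_reject < alpha_accept,
    alpha_accept > 0, alpha_accept < 1, alpha_reject > 0
  )
  indices <- match.arg(indices, several.ok = TRUE)
  collapse_strategies <- intersect(collapse_strategies, c("shallow", "all"))
  structure(
    list(
      tree_sizes = as.integer(tree_sizes), n_trees = as.integer(n_trees),
      lambda_grid = lambda_grid,
      collapse_fractions = collapse_fractions,
      collapse_strategies = collapse_strategies,
      fix_fractions = fix_fractions, combined = isTRUE(combined),
      indices = indices, n_perm = as.integer(n_perm),
      alpha_accept = alpha_accept, alpha_reject = alpha_reject,
      birth_rate = birth_rate, n_slices = as.integer(n_slices),
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Classify a paired test outcome as a directional bias
#'
#' The dual-alpha screen for strong p-value shifts between a true
#' chronogram and its degraded counterpart. A pair is a type I bias when
#' the no-signal null is accepted on the true tree
#' (`p_true > alpha_accept`) but rejected on the degraded tree
#' (`p_degraded < alpha_reject`); a type II bias is the converse
#' (`p_true < alpha_reject`, `p_degraded > alpha_accept`). Marginal cases
#' are screened out by the two different alpha levels and classified as
#' `"none"`.
#'
#' @param p_true,p_degraded p-values from the same trait on the true and
#'   degraded tree; vectors recycle.
#' @param alpha_accept,alpha_reject Screen levels (defaults 0.05 and
#'   0.01).
#' @return Character vector in `c("none", "typeI", "typeII")`.
#' @examples
#' classify_bias(c(0.20, 0.005, 0.03), c(0.005, 0.20, 0.005))
#' @export
classify_bias <- function(p_true, p_degraded, alpha_accept = 0.05,
                          alpha_reject = 0.01) {
  if (any(p_true <= 0 | p_true > 1, na.rm = FALSE) ||
    any(p_degraded <= 0 | p_degraded > 1) ||
    anyNA(p_true) || anyNA(p_degraded)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  out <- rep("none", length(p_true))
  out[p_true > alpha_accept & p_degraded < alpha_reject] <- "typeI"
  out[p_true < alpha_reject & p_degraded > alpha_accept] <- "typeII"
  out
}

#' Frequencies of directional biases from paired results
#'
#' Joins every degraded-tree result row to the true-chronogram row of the
#' same tree and trait, classifies each pair with [classify_bias()], and
#' tabulates type I and type II frequencies per cell of the design
#' (signal index, treatment, tree size, degradation level, trait-signal
#' level). The denominator is all pairs in the cell; with
#' `conditional = TRUE` it is instead the number of pairs eligible for
#' the respective bias (true-tree p-value above `alpha_accept` for type I,
#' below `alpha_reject` for type II). Design cells with no pairs are kept
#' with `n_pairs = 0` and `NA` frequencies.
#'
#' @param results Long results tibble from [run_experiment()] (or the same
#'   shape), containing a `treatment == "true"` stratum.
#' @param alpha_accept,alpha_reject Screen levels.
#' @param conditional Use conditional denominators (default `FALSE`).
#' @return A `bias_table` tibble with columns `index`, `treatment`,
#'   `n_tips`, `level`, `lambda_sim`, `n_pairs`, `freq_typeI`,
#'   `freq_typeII`.
#' @export
bias_frequencies <- function(results, alpha_accept = 0.05,
                             alpha_reject = 0.01, conditional = FALSE) {
  truth <- results |>
    dplyr::filter(.data$treatment == "true") |>
    dplyr::select(
      "tree_id", "n_tips", "lambda_sim",
      dplyr::any_of(c(p_K_true = "p_K", p_lambda_true = "p_lambda"))
    )
  deg <- results |>
    dplyr::filter(.data$treatment != "true") |>
    dplyr::inner_join(truth, by = c("tree_id", "n_tips", "lambda_sim"))

  long <- list()
  if ("p_K" %in% names(results) && !all(is.na(results$p_K))) {
    long$K <- deg |>
      dplyr::transmute(
        index = "K", .data$treatment, .data$n_tips, .data$level,
        .data$lambda_sim,
        p_true = .data$p_K_true, p_deg = .data$p_K
      )
  }
  if ("p_lambda" %in% names(results) && !all(is.na(results$p_lambda))) {
    long$lambda <- deg |>
      dplyr::transmute(
        index = "lambda", .data$treatment, .data$n_tips, .data$level,
        .data$lambda_sim,
        p_true = .data$p_lambda_true, p_deg = .data$p_lambda
      )
  }
  pairs <- dplyr::bind_rows(long)
  pairs$bias <- classify_bias(
    pairs$p_true, pairs$p_deg,
    alpha_accept, alpha_reject
  )
  tab <- pairs |>
    dplyr::group_by(
      .data$index, .data$treatment, .data$n_tips, .data$level,
      .data$lambda_sim
    ) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      freq_typeI = if (conditional) {
        n_elig <- sum(.data$p_true > alpha_accept)
        if (n_elig == 0) NA_real_ else sum(.data$bias == "typeI") / n_elig
      } else {
        mean(.data$bias == "typeI")
      },
      freq_typeII = if (conditional) {
        n_elig <- sum(.data$p_true < alpha_reject)
        if (n_elig == 0) NA_real_ else sum(.data$bias == "typeII") / n_elig
      } else {
        mean(.data$bias == "typeII")
      },
      .groups = "drop"
    )
  # keep empty design cells visible: full grid of observed margins
  grid <- tidyr::expand_grid(
    index = unique(tab$index),
    dplyr::distinct(tab, .data$treatment, .data$level),
    n_tips = unique(tab$n_tips),
    lambda_sim = unique(tab$lambda_sim)
  )
  tab <- grid |>
    dplyr::left_join(
      tab,
      by = c("index", "treatment", "level", "n_tips", "lambda_sim")
    ) |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L)) |>
    dplyr::arrange(
      .data$index, .data$treatment, .data$level, .data$n_tips,
      .data$lambda_sim
    )
  class(tab) <- c("bias_table", class(tab))
  tab
}

#' Stratify trees by tree shape
#'
#' Assigns each tree to the lower or upper tail of the distribution of a
#' shape statistic within its size category: lower means at or below the
#' 10th percentile, upper at or above the 90th (linear-interpolation
#' percentiles, inclusive comparisons). Colless stratification applies to
#' the binary true chronograms only.
#'
#' @param shape Tibble from [shape_stats()] (must include `tree_id`,
#'   `n_tips` and the chosen statistic).
#' @param stat `"gamma"` or `"colless"`.
#' @param lower_q,upper_q Percentile cutoffs (defaults 0.1 and 0.9).
#' @return The input restricted to stratified trees, with a `stratum`
#'   column (`"lower"` / `"upper"`).
#' @export
stratify_by_shape <- function(shape, stat = c("gamma", "colless"),
                              lower_q = 0.1, upper_q = 0.9) {
  stat <- match.arg(stat)
  out <- shape |>
    dplyr::group_by(.data$n_tips) |>
    dplyr::mutate(
      .lo = stats::quantile(.data[[stat]], lower_q, na.rm = TRUE, names = FALSE),
      .hi = stats::quantile(.data[[stat]], upper_q, na.rm = TRUE, names = FALSE),
      stratum = dplyr::case_when(
        .data[[stat]] <= .data$.lo ~ "lower",
        .data[[stat]] >= .data$.hi ~ "upper",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$stratum)) |>
    dplyr::select(-".lo", -".hi")
  small <- out |>
    dplyr::count(.data$n_tips, .data$stratum) |>
    dplyr::filter(.data$n < 5L)
  if (nrow(small)) {
    warning("some shape strata contain fewer than 5 trees", call. = FALSE)
  }
  out
}

#' Run the full degradation-sensitivity experiment
#'
#' For every tree of the design: simulate a pure-birth chronogram, record
#' its shape statistics, build all degraded versions (polytomic
#' chronograms for each collapse strategy and fraction, pseudo-chronograms
#' for each fix fraction, optionally their combination), simulate the
#' trait-signal grid once on the true tree, and run the requested signal
#' tests on the true tree and on every degraded version with the same
#' trait vectors. Bias frequencies and shape-stratified bias frequencies
#' are tabulated at the end.
#'
#' Every stochastic stage derives its seed from the master seed, so a
#' rerun with the same configuration is bit-identical. When `out_dir` is
#' given, per-tree result chunks are written under
#' `out_dir/results_by_tree/` and reused on a rerun (per-tree
#' resumability), and the final tables (`results.tsv`, `shape.tsv`,
#' `bias_table.tsv`, the stratified bias tables and `manifest.yaml`) are
#' written alongside. Per-tree failures are recorded in the manifest and
#' skipped.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory.
#' @param progress Print one line per completed tree (default `FALSE`).
#' @return A list: `results` (per-replicate signal fits), `shape`,
#'   `bias` (a `bias_table`), `bias_by_shape` (list of bias tables for the
#'   gamma/colless lower and upper strata), `manifest`, `config`.
#' @examples
#' cfg <- experiment_config(
#'   tree_sizes = 50, n_trees = 2, lambda_grid = c(0.2, 0.8),
#'   collapse_fractions = 0.4, collapse_strategies = "shallow",
#'   fix_fractions = 0.15, n_perm = 49, seed = 1
#' )
#' run <- run_experiment(cfg)
#' run$bias
#' @export
run_experiment <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  chunk_dir <- NULL
  if (!is.null(out_dir)) {
    chunk_dir <- file.path(out_dir, "results_by_tree")
    dir.create(chunk_dir, recursive = TRUE, showWarnings = FALSE)
  }
  shape_rows <- list()
  result_rows <- list()
  failed <- character()

  for (n in config$tree_sizes) {
    for (i in seq_len(config$n_trees)) {
      tree_id <- sprintf("n%d_r%03d", n, i)
      chunk_file <- if (!is.null(chunk_dir)) {
        file.path(chunk_dir, paste0(tree_id, ".tsv"))
      }
      res <- tryCatch(
        run_one_tree(config, n, i, tree_id, chunk_file),
        error = function(e) {
          warning(sprintf("tree %s failed: %s", tree_id, conditionMessage(e)),
            call. = FALSE
          )
          NULL
        }
      )
      if (is.null(res)) {
        failed <- c(failed, tree_id)
        next
      }
      shape_rows[[tree_id]] <- res$shape
      result_rows[[tree_id]] <- res$results
      if (progress) {
        message(sprintf("done %s (%d rows)", tree_id, nrow(res$results)))
      }
    }
  }

  results <- dplyr::bind_rows(result_rows)
  shape <- dplyr::bind_rows(shape_rows)
  bias <- bias_frequencies(results, config$alpha_accept, config$alpha_reject)

  by_shape <- list()
  for (stat in c("gamma", "colless")) {
    strat <- suppressWarnings(stratify_by_shape(shape, stat))
    for (side in c("lower", "upper")) {
      ids <- strat$tree_id[strat$stratum == side]
      key <- paste(stat, side, sep = "_")
      by_shape[[key]] <- bias_frequencies(
        dplyr::filter(results, .data$tree_id %in% ids),
        config$alpha_accept, config$alpha_reject
      )
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("signalbias")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_trees_requested = length(config$tree_sizes) * config$n_trees,
    n_trees_failed = length(failed),
    failed = failed
  )

  if (!is.null(out_dir)) {
    write_tsv_plain(results, file.path(out_dir, "results.tsv"))
    write_tsv_plain(shape, file.path(out_dir, "shape.tsv"))
    write_tsv_plain(bias, file.path(out_dir, "bias_table.tsv"))
    for (key in names(by_shape)) {
      write_tsv_plain(
        by_shape[[key]],
        file.path(out_dir, sprintf("bias_table_%s.tsv", key))
      )
    }
    write_manifest(c(manifest, list(config = unclass(config))),
      file.path(out_dir, "manifest.yaml")
    )
  }

  list(
    results = results, shape = shape, bias = bias, bias_by_shape = by_shape,
    manifest = manifest, config = config
  )
}

# one tree of the design: simulate, degrade, fit; cached per tree when a
# chunk file is given
run_one_tree <- function(config, n, i, tree_id, chunk_file = NULL) {
  stream <- paste0("tree_", n)
  tr <- sim_pure_birth(n,
    birth_rate = config$birth_rate,
    seed = child_seed(config$seed, stream, i)
  )
  shape <- shape_stats(stats::setNames(list(tr), tree_id))

  if (!is.null(chunk_file) && file.exists(chunk_file)) {
    res <- tibble::as_tibble(utils::read.delim(chunk_file,
      colClasses = c(
        tree_id = "character", treatment = "character",
        level = "character"
      )
    ))
    return(list(shape = shape, results = res))
  }

  traits <- simulate_traits(tr, config$lambda_grid,
    seed = child_seed(config$seed, paste0("traits_", n), i)
  )

  versions <- list(true = list(tree = tr, level = ""))
  ctr <- 0L
  for (strategy in config$collapse_strategies) {
    for (f in config$collapse_fractions) {
      ctr <- ctr + 1L
      versions[[paste0("polytomic_", strategy, ".", f)]] <- list(
        tree = collapse_nodes(tr, f,
          strategy = strategy,
          seed = child_seed(config$seed, paste0("collapse_", n, "_", i), ctr)
        ),
        treatment = paste0("polytomic_", strategy), level = format(f)
      )
    }
  }
  for (f in config$fix_fractions) {
    ctr <- ctr + 1L
    fixed <- select_fixed_nodes(tr, f,
      n_slices = config$n_slices,
      seed = child_seed(config$seed, paste0("fix_", n, "_", i), ctr)
    )
    versions[[paste0("pseudo.", f)]] <- list(
      tree = bladj_calibrate(tr, fixed), treatment = "pseudo",
      level = format(f)
    )
  }
  if (config$combined) {
    for (f1 in config$fix_fractions) {
      for (f2 in config$collapse_fractions) {
        ctr <- ctr + 1L
        versions[[paste0("combined.", f1, ".", f2)]] <- list(
          tree = make_polytomic_pseudochronogram(tr, f1, f2,
            n_slices = config$n_slices,
            seed = child_seed(config$seed, paste0("comb_", n, "_", i), ctr)
          ),
          treatment = "combined", level = paste(format(f1), format(f2),
            sep = "/"
          )
        )
      }
    }
  }

  rows <- list()
  for (vname in names(versions)) {
    v <- versions[[vname]]
    treatment <- v$treatment %||% "true"
    basis <- signal_basis(v$tree)
    for (j in seq_along(config$lambda_grid)) {
      lam <- config$lambda_grid[j]
      x <- traits$value[traits$lambda_sim == lam]
      names(x) <- traits$tip[traits$lambda_sim == lam]
      k <- NA_real_
      p_k <- NA_real_
      lam_hat <- NA_real_
      lnl_hat <- NA_real_
      lnl0 <- NA_real_
      p_lam <- NA_real_
      if ("K" %in% config$indices) {
        k <- blomberg_k(x, v$tree, basis = basis)
        p_k <- as.numeric(k_perm_test(x, v$tree,
          n_perm = config$n_perm, basis = basis,
          seed = child_seed(config$seed, paste0("perm_", tree_id, "_", vname), j)
        ))
      }
      if ("lambda" %in% config$indices) {
        pl <- lambda_lrt(x, v$tree, basis = basis)
        lam_hat <- attr(pl, "lambda_hat")
        lnl_hat <- attr(pl, "lnL_hat")
        lnl0 <- attr(pl, "lnL0")
        p_lam <- as.numeric(pl)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tree_id = tree_id, n_tips = n, treatment = treatment,
        level = v$level, lambda_sim = lam,
        K = k, p_K = p_k, lambda_hat = lam_hat, lnL_hat = lnl_hat,
        lnL0 = lnl0, p_lambda = p_lam, n_perm = config$n_perm
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  if (!is.null(chunk_file)) write_tsv_plain(res, chunk_file)
  list(shape = shape, results = res)
}

write_tsv_plain <- function(df, path) {
  # doubles at 17 significant digits so a read-back is bit-exact
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(v) sprintf("%.17g", v)
  ))
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

# minimal flat YAML writer for the run manifest (scalars and flat lists)
write_manifest <- function(x, path) {
  fmt <- function(key, val, indent = "") {
    if (is.list(val)) {
      c(
        paste0(indent, key, ":"),
        unlist(purrr::imap(val, function(v, k) fmt(k, v, paste0(indent, "  "))))
      )
    } else if (length(val) == 0L) {
      paste0(indent, key, ": []")
    } else if (length(val) > 1L) {
      paste0(
        indent, key, ": [",
        paste(vapply(val, format, ""), collapse = ", "), "]"
      )
    } else {
      paste0(indent, key, ": ", format(val))
    }
  }
  writeLines(unlist(purrr::imap(x, function(v, k) fmt(k, v))), path)
}
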