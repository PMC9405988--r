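# End-to-end orchestration: simulate/ingest -> grouping -> per-band PLV
# -> per-(band, segment, group) permutation tests -> distances / Gcst /
# band selection -> tvDFC on the selected band -> regressions -> hubs.

#' Pipeline configuration
#'
#' @param simulate A [sim_config()] to generate data on the fly, or
#'   `NULL` to read an existing dataset from `input_dir`.
#' @param input_dir Dataset directory (as written by [write_dataset()]);
#'   required when `simulate` is `NULL`.
#' @param out_dir Output directory for all result files.
#' @param bands Band table (default all six from [eeg_bands()]).
#' @param k_groups Number of emotion groups (default 8).
#' @param alpha_edges FWER level for connection significance (0.01).
#' @param alpha_hubs Hub significance level (0.05).
#' @param n_perm Permutations per significance test (default 1000).
#' @param n_random_graphs Erdos-Renyi null size for hubs (default 10000).
#' @param n_baseline_per_subject Baseline epochs per subject; default
#'   `NULL` means "that subject's retained event count", balancing the
#'   two conditions of the permutation test.
#' @param band_override Force tvDFC/regression/hubs onto this band
#'   instead of the Gcst-selected one.
#' @param filter_order Butterworth prototype order (default 4).
#' @param write_edge_tsvs Write one edge-list TSV per (band, segment,
#'   group)? Default TRUE.
#' @param seed Root seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            out_dir = tempfile("emodfc-run-"),
                            bands = eeg_bands(), k_groups = 8,
                            alpha_edges = 0.01, alpha_hubs = 0.05,
                            n_perm = 1000, n_random_graphs = 10000,
                            n_baseline_per_subject = NULL,
                            band_override = NULL, filter_order = 4,
                            write_edge_tsvs = TRUE, seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(input_dir)) {
      stop("config error: either a simulate block or input_dir is required")
    }
    if (!file.exists(file.path(input_dir, "manifest.json"))) {
      stop("config error: no manifest.json under ", input_dir)
    }
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  for (a in c(alpha_edges, alpha_hubs)) {
    if (!(a > 0 && a < 1)) stop("config error: alphas must lie in (0, 1)")
  }
  structure(list(
    simulate = simulate, input_dir = input_dir, out_dir = out_dir,
    bands = bands, k_groups = k_groups, alpha_edges = alpha_edges,
    alpha_hubs = alpha_hubs, n_perm = n_perm,
    n_random_graphs = n_random_graphs,
    n_baseline_per_subject = n_baseline_per_subject,
    band_override = band_override, filter_order = filter_order,
    write_edge_tsvs = write_edge_tsvs, seed = as.integer(seed)
  ), class = "pipeline_config")
}

run_log <- function(path, ...) {
  line <- paste0(...)
  message(line)
  if (!is.null(path)) cat(line, "\n", file = path, append = TRUE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes all tables, summaries and a
#' manifest under `cfg$out_dir`. Re-running with an identical
#' configuration reproduces identical TSV/JSON outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return list with the in-memory results of every stage (`grouping`,
#'   `gcst`, `band_tests`, `selected_band`, `tv_records`, `lmm_fits`,
#'   `logistic_fit`, `hubs`, `manifest`, ...), invisibly usable for
#'   further analysis.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  files <- character(0)

  ds <- stage("ingest", {
    if (!is.null(cfg$simulate)) {
      data_dir <- file.path(cfg$out_dir, "data")
      write_dataset(cfg$simulate, data_dir)
      read_dataset(data_dir)
    } else {
      read_dataset(cfg$input_dir)
    }
  })
  run_log(log_path, "ingest: ", length(ds$recordings), " subjects, ",
          nrow(ds$events), " events")

  events <- stage("event-filter", drop_overlapping_events(ds$events))
  run_log(log_path, "event-filter: ", nrow(ds$events) - nrow(events),
          " overlapping events dropped, ", nrow(events), " retained")

  grouping <- stage("grouping",
                    group_labels(label_va_means(events), k = cfg$k_groups))
  events <- stage("grouping", assign_groups(events, grouping))
  gr_path <- file.path(cfg$out_dir, "emotion_groups.tsv")
  utils::write.table(grouping, gr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, gr_path)

  # epoch extraction + band decomposition, subject by subject
  epochs <- stage("epochs", {
    ev_ep <- list(); bl_ep <- list(); ev_rows <- list()
    for (sid in names(ds$recordings)) {
      rec <- ds$recordings[[sid]]
      rec <- bandpass_filter(rec, 1, 40, cfg$filter_order)
      sev <- events[as.character(events$subject) == sid, , drop = FALSE]
      if (!nrow(sev)) next
      for (r in seq_len(nrow(sev))) {
        ev_ep[[length(ev_ep) + 1]] <- extract_event_epoch(rec, sev[r, ])
        ev_rows[[length(ev_rows) + 1]] <- sev[r, ]
      }
      # default: match the subject's event count, capped at the packing
      # bound of the 60-s baseline span (floor(60 / 7) = 8 windows)
      nb <- min(cfg$n_baseline_per_subject %||% nrow(sev), 8)
      bl <- extract_baseline_epochs(
        rec, nb, seed = derive_seed(cfg$seed, 90000L + as.integer(sid)))
      bl_ep <- c(bl_ep, bl)
    }
    list(ev = ev_ep, bl = bl_ep, ev_table = do.call(rbind, ev_rows))
  })
  run_log(log_path, "epochs: ", length(epochs$ev), " event + ",
          length(epochs$bl), " baseline epochs")

  bands <- cfg$bands
  decomposed <- stage("band-decompose", {
    lapply(c(epochs$ev, epochs$bl), band_decompose, bands = bands,
           order = cfg$filter_order)
  })
  n_ev <- length(epochs$ev)
  ev_table <- epochs$ev_table
  channels <- epochs$ev[[1]]$channels

  # per-band PLV tensors for events and baselines
  tensors <- stage("plv", {
    out <- list()
    for (b in bands$name) {
      all_b <- lapply(decomposed, `[[`, b)
      out[[b]] <- list(
        ev = plv_tensor(all_b[seq_len(n_ev)]),
        bl = plv_tensor(all_b[(n_ev + 1):length(all_b)])
      )
    }
    out
  })
  pairs <- tensors[[1]]$ev$pairs
  n_seg <- nrow(tensors[[1]]$ev$windows)

  # per-(band, segment, group) permutation tests + connectivity vectors
  groups_present <- sort(unique(ev_table$group))
  usable <- groups_present[vapply(groups_present, function(g)
    sum(ev_table$group == g) >= 2, logical(1))]
  if (length(usable) < length(groups_present)) {
    run_log(log_path, "permtest: skipping group(s) with < 2 events: ",
            paste(setdiff(groups_present, usable), collapse = ", "))
  }
  bl_subjects <- vapply(epochs$bl, function(e) as.character(e$subject), "")
  sig_store <- list()
  conn_store <- list()
  stage("permtest", {
    k <- 0L
    for (b in bands$name) {
      for (g in usable) {
        ge <- which(ev_table$group == g)
        gsub <- as.character(ev_table$subject[ge])
        blx <- which(bl_subjects %in% gsub)
        for (s in seq_len(n_seg)) {
          k <- k + 1L
          sig <- max_stat_test(
            tensors[[b]]$ev$values[ge, s, , drop = TRUE],
            tensors[[b]]$bl$values[blx, s, , drop = TRUE],
            gsub, bl_subjects[blx],
            alpha = cfg$alpha_edges, n_perm = cfg$n_perm,
            seed = derive_seed(cfg$seed, 1000L + k))
          key <- paste(b, s, g, sep = "|")
          sig_store[[key]] <- sig
          mean_plv <- colMeans(
            tensors[[b]]$ev$values[ge, s, , drop = FALSE][, 1, ])
          conn_store[[key]] <- connectivity_vector(sig, mean_plv)
          run_log(log_path, sprintf(
            "permtest band=%s seg=%d group=%d n_perm=%d seed=%d sig=%d",
            b, s - 1, g, cfg$n_perm, derive_seed(cfg$seed, 1000L + k),
            sum(sig$mask)))
          if (cfg$write_edge_tsvs) {
            ed <- file.path(cfg$out_dir, sprintf(
              "edges_%s_seg%d_group%d.tsv", b, s - 1, g))
            write_significance_tsv(sig, pairs, ed)
            files <- c(files, ed)
          }
        }
      }
    }
  })

  # distances, Gcst, band selection
  dist_table <- stage("distances", {
    rows <- list()
    for (b in bands$name) {
      for (s in seq_len(n_seg)) {
        vecs <- stats::setNames(
          lapply(usable, function(g) conn_store[[paste(b, s, g, sep = "|")]]),
          as.character(usable))
        d <- group_pair_distances(vecs)
        d$band <- b; d$segment <- s - 1
        rows[[length(rows) + 1]] <- d
      }
    }
    do.call(rbind, rows)
  })
  dt_path <- file.path(cfg$out_dir, "distances.tsv")
  utils::write.table(dist_table, dt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, dt_path)

  band_avgs <- stage("distances", {
    stats::setNames(lapply(bands$name, function(b)
      band_average_distances(dist_table, b, n_segments = n_seg)),
      bands$name)
  })
  gcst <- global_threshold(band_avgs)
  band_tests <- stage("band-selection", {
    lapply(band_avgs, function(av) {
      tryCatch(band_selection_test(av, gcst = gcst, n_bands = nrow(bands)),
               error = function(e) {
                 # all-zero (or constant) distances: nothing to select
                 list(t = 0, df = nrow(av) - 1, p = 1, p_raw = 1,
                      cohens_d = 0, selected = FALSE, degenerate = TRUE)
               })
    })
  })
  sel_names <- names(band_tests)[vapply(band_tests, `[[`, logical(1),
                                        "selected")]
  best <- names(band_tests)[which.max(vapply(band_tests, `[[`,
                                             numeric(1), "t"))]
  selected_band <- cfg$band_override %||%
    (if (length(sel_names)) sel_names[which.max(
      vapply(band_tests[sel_names], `[[`, numeric(1), "t"))] else best)
  # pairwise comparison of the two most discriminative bands
  t_ord <- order(vapply(band_tests, `[[`, numeric(1), "t"),
                 decreasing = TRUE)
  top2 <- names(band_tests)[t_ord[1:2]]
  pair_cmp <- paired_band_comparison(band_avgs[[top2[1]]]$distance,
                                     band_avgs[[top2[2]]]$distance)
  run_log(log_path, "band-selection: Gcst = ", signif(gcst, 4),
          "; selected band = ", selected_band)
  summary_json <- list(
    gcst = gcst,
    bands = lapply(band_tests, function(bt)
      bt[c("t", "df", "p", "p_raw", "cohens_d", "selected")]),
    selected_band = selected_band,
    top_band_comparison = c(list(bands = top2),
                            pair_cmp[c("t", "df", "p", "cohens_d")])
  )
  sj_path <- file.path(cfg$out_dir, "band_summary.json")
  jsonlite::write_json(summary_json, sj_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, sj_path)

  # tvDFC per event on the selected band
  tv_records <- stage("tvdfc", {
    rows <- list()
    for (e in seq_len(n_ev)) {
      g <- ev_table$group[e]
      if (!g %in% usable) next
      segvec <- t(vapply(seq_len(n_seg), function(s) {
        sig <- sig_store[[paste(selected_band, s, g, sep = "|")]]
        ifelse(sig$mask, tensors[[selected_band]]$ev$values[e, s, ], 0)
      }, numeric(nrow(pairs))))
      row <- ev_table[e, c("subject", "onset", "emotion", "group",
                           "valence", "arousal", "dominance", "liking",
                           "familiarity", "relevance")]
      row$event <- e
      row$band <- selected_band
      row$tv <- temporal_variability(segvec)
      rows[[length(rows) + 1]] <- row
    }
    do.call(rbind, rows)
  })
  tv_path <- file.path(cfg$out_dir, "tv_records.tsv")
  utils::write.table(tv_records, tv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, tv_path)

  # regressions
  scales <- c("valence", "arousal", "dominance", "liking", "familiarity",
              "relevance")
  lmm_fits <- stage("regress", {
    fits <- lapply(scales, function(sc) {
      if (stats::sd(tv_records[[sc]]) == 0 ||
          stats::sd(tv_records$tv) == 0) return(NULL)
      fit_scale_on_tv(tv_records, sc)
    })
    stats::setNames(fits, scales)
  })
  logistic_fit <- stage("regress", {
    tryCatch(fit_interaction_logistic(tv_records),
             error = function(e) list(error = conditionMessage(e)))
  })
  mod_rows <- do.call(rbind, lapply(Filter(Negate(is.null), lmm_fits),
    function(f) data.frame(scale = f$scale, beta = f$beta, se = f$se,
                           ci_lo = f$ci95[1], ci_hi = f$ci95[2],
                           t = f$t, p = f$p, n_obs = f$n_obs,
                           converged = f$converged)))
  mr_path <- file.path(cfg$out_dir, "regressions.tsv")
  utils::write.table(mod_rows, mr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, mr_path)
  for (f in Filter(Negate(is.null), lmm_fits)) {
    p <- file.path(cfg$out_dir, paste0("model_", f$scale, ".json"))
    jsonlite::write_json(
      f[c("scale", "beta", "se", "ci95", "t", "df", "p", "n_obs",
          "n_subjects", "converged", "method")],
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, p)
  }

  # hubs on the selected band: union over segments and groups of
  # significant connections, weighted by mean PLV
  hubs <- stage("hubs", {
    nch <- length(channels)
    W <- matrix(0, nch, nch)
    Cnt <- matrix(0, nch, nch)
    for (g in usable) {
      for (s in seq_len(n_seg)) {
        v <- conn_store[[paste(selected_band, s, g, sep = "|")]]
        on <- which(v > 0)
        for (p in on) {
          i <- pairs$i[p]; j <- pairs$j[p]
          W[i, j] <- W[i, j] + v[p]
          Cnt[i, j] <- Cnt[i, j] + 1
        }
      }
    }
    W <- ifelse(Cnt > 0, W / pmax(Cnt, 1), 0)
    W <- W + t(W)
    rownames(W) <- colnames(W) <- channels
    if (all(W == 0)) {
      run_log(log_path, "hubs: no significant connections; skipping")
      NULL
    } else {
      hub_significance(W, n_random = cfg$n_random_graphs,
                       alpha = cfg$alpha_hubs,
                       seed = derive_seed(cfg$seed, 777L))
    }
  })
  if (!is.null(hubs)) {
    hb_path <- file.path(cfg$out_dir, "hubs.tsv")
    utils::write.table(hubs, hb_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, hb_path)
  }

  cfg_path <- file.path(cfg$out_dir, "config.json")
  cfg_json <- cfg[setdiff(names(cfg), c("simulate", "bands"))]
  cfg_json$simulate <- if (!is.null(cfg$simulate))
    unclass(cfg$simulate) else NULL
  cfg_json$bands <- cfg$bands$name
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, cfg_path)
  manifest <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    selected_band = selected_band,
    gcst = gcst,
    n_events = n_ev,
    n_groups = length(usable),
    files = sort(basename(files))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(log_path, "done: ", length(files), " output files in ",
          cfg$out_dir)

  invisible(list(
    config = cfg, events = events, grouping = grouping,
    pairs = pairs, tensors = tensors, significance = sig_store,
    connectivity = conn_store, distances = dist_table,
    band_averages = band_avgs, gcst = gcst, band_tests = band_tests,
    band_comparison = pair_cmp, selected_band = selected_band,
    tv_records = tv_records, lmm_fits = lmm_fits,
    logistic_fit = logistic_fit, hubs = hubs, manifest = manifest
  ))
}
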