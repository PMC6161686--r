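# Orchestration: one configuration document covering every module's
# thresholds, stage-wise logging, and a combined per-locus report.

#' Default pipeline configuration
#'
#' One document holding every tunable of the pipeline: the simulation
#' scenario, the calling thresholds, the extent/readthrough knobs, and the
#' motif search parameters. Unknown keys are rejected.
#'
#' @param seed seed forwarded to the scenario.
#' @param ... overrides, either top-level sections or leaf values inside
#'   `scenario`, `thresholds`, `extent`, `motif`.
#' @return nested named list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    scenario = unclass(sim_scenario(seed)),
    thresholds = call_thresholds(),
    extent = list(min_depth = 1, pad = 100L, max_gap = 50L, a_frac = 0.8),
    motif = list(window = 140L, min_run = 8L, upstream_span = 30L))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    if (is.list(dots[[nm]])) {
      bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config key: ", nm, "$", bad[1L])
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file may override any subset of [default_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @param seed seed if the file does not set one.
#' @return config list.
#' @export
read_config <- function(path, seed = 1) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$seed)) seed <- y$seed
  do.call(default_config, c(list(seed = seed),
                            y[setdiff(names(y), "seed")]))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages: simulate, classify (size histogram + 21-nt category fractions per
#' condition), call (per-locus criteria verdicts), extent (pri-transcript
#' extents, enrichment, readthrough), termini (tail calls and spectrum, TSS
#' motifs, PFM), report (joined per-locus table). All outputs are TSV files
#' carrying the config hash in a header comment; everything is
#' deterministic under (config, seed).
#'
#' @param config from [default_config()] or [read_config()].
#' @param outdir output directory; created if needed. NULL = no files.
#' @param log write stage progress to stderr.
#' @return invisibly, a list with all in-memory results (`sim`, `classes`,
#'   `calls`, `extents`, `readthrough`, `tails`, `motifs`, `pfm`, `report`).
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         log = TRUE) {
  say <- function(...) if (log) message("[", format(Sys.time(), "%H:%M:%S"),
                                        "] ", ...)
  hash <- config_hash(config)
  hdr <- c(config_md5 = hash, seed = config$seed)
  wout <- function(df, name) {
    if (!is.null(outdir)) write_report(df, file.path(outdir, name), hdr)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeLines(yaml::as.yaml(config), file.path(outdir, "config_echo.yaml"))
  }
  scenario <- do.call(sim_scenario, c(
    list(seed = config$seed),
    config$scenario[setdiff(names(config$scenario), "seed")]))

  say("simulate: genome + 4 libraries + coverage")
  sim <- simulate_dataset(scenario)
  say("simulate: ", nrow(sim$truth$loci), " planted loci, ",
      sum(vapply(sim$reads, nrow, integer(1))), " reads")
  if (!is.null(outdir)) write_simulation(sim, file.path(outdir, "sim"))

  say("classify: size histograms and 21-nt class fractions")
  classes <- list()
  for (cond in names(sim$reads)) {
    hist <- size_histogram(sim$reads[[cond]])
    frac <- category_fractions(sim$reads[[cond]], sim$features)
    classes[[cond]] <- list(hist = hist, fractions = frac)
    wout(cbind(condition = cond, hist), sprintf("sizes_%s.tsv", cond))
    wout(cbind(condition = cond, frac), sprintf("classes_%s.tsv", cond))
  }

  say("call: criteria engine over ", nrow(sim$truth$loci), " candidates")
  calls <- call_all_loci(sim$genome, sim$truth$loci, sim$reads,
                         config$thresholds)
  say("call: ", sum(calls$summary$tier == "high_confidence"),
      " high-confidence / ", sum(calls$summary$tier == "candidate"),
      " candidate / ", sum(calls$summary$tier == "reject"), " rejected")
  wout(calls$summary, "locus_calls.tsv")

  say("extent: transcript extents and knockout enrichment")
  mir <- sim$truth$loci[sim$truth$loci$class == "mirna", ]
  extents <- extent_table(mir, sim$coverage, config$extent$min_depth,
                          config$extent$pad)
  wout(extents, "extents.tsv")
  rt <- NULL
  rt_locus <- mir[isTRUE_vec(mir$readthrough), ]
  if (nrow(rt_locus)) {
    l <- rt_locus[1L, ]
    dsg <- list(start = l$dsg_start, end = l$dsg_end)
    rt <- list(
      wt = detect_readthrough(sim$coverage$wt[[l$strand]], l, dsg,
                              sim$genome, config$extent$max_gap,
                              config$extent$a_frac),
      ko = detect_readthrough(sim$coverage$ko[[l$strand]], l, dsg,
                              sim$genome, config$extent$max_gap,
                              config$extent$a_frac))
    say("extent: readthrough at ", l$locus_id, ": wt=", rt$wt$bridged,
        " ko=", rt$ko$bridged)
  }

  say("termini: tail calls and TSS motifs")
  tl_locus <- mir[!is.na(mir$tail_site1), ][1L, ]
  tails <- tail_calls(sim$tailed, sim$genome, anchor = tl_locus$anchor,
                      strand = tl_locus$strand)
  wout(tails, "tails.tsv")
  spectrum <- tail_spectrum(tails)
  wout(spectrum, "tail_spectrum.tsv")

  motifs <- list()
  for (i in seq_len(nrow(mir))) {
    l <- mir[i, ]
    tr <- sim$coverage$ko[[l$strand]]
    ext <- transcript_extent(tr, list(anchor = l$anchor, strand = l$strand,
                                      span_start = min(l$tss, l$pri_end) -
                                        config$extent$pad,
                                      span_end = max(l$tss, l$pri_end) + 1L +
                                        config$extent$pad),
                             config$extent$min_depth)
    if (is.null(ext)) next
    anchor5 <- from_relative(ext$five_prime_most, l$anchor, l$strand)
    hits <- find_tss_motif(sim$genome, anchor5, l$strand,
                           config$motif$window, config$motif$min_run)
    if (nrow(hits))
      motifs[[length(motifs) + 1L]] <-
        cbind(locus_id = l$locus_id, strand = l$strand, hits[1L, ])
  }
  motifs <- do.call(rbind, motifs)
  wout(motifs, "tss_motifs.tsv")
  pfm <- if (!is.null(motifs) && nrow(motifs))
    build_pfm(motifs, sim$genome, config$motif$upstream_span) else NULL
  if (!is.null(pfm) && !is.null(outdir))
    write_report(cbind(base = rownames(pfm), as.data.frame(pfm)),
                 file.path(outdir, "tss_pfm.tsv"), hdr)

  say("report: joining per-locus results")
  report <- merge(calls$summary,
                  sim$truth$loci[, c("locus_id", "class", "violation",
                                     "strand", "mor")],
                  by = "locus_id", all.x = TRUE)
  report <- merge(report, extents, by = "locus_id", all.x = TRUE)
  if (!is.null(motifs) && nrow(motifs))
    report <- merge(report, motifs[, c("locus_id", "predicted_tss",
                                       "run_length")],
                    by = "locus_id", all.x = TRUE)
  report <- report[order(report$locus_id), ]
  wout(report, "report.tsv")
  say("done")
  invisible(list(config = config, sim = sim, classes = classes,
                 calls = calls, extents = extents, readthrough = rt,
                 tails = tails, spectrum = spectrum, motifs = motifs,
                 pfm = pfm, report = report))
}

isTRUE_vec <- function(x) !is.na(x) & x
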