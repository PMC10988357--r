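#' Default pipeline configuration
#'
#' Parameters of every stage of the end-to-end run, with an explicit seed
#' for each random stage. The configuration round-trips losslessly through
#' YAML ([yaml::write_yaml()] / [yaml::read_yaml()]).
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param out_dir Output directory of the run.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("vocalmod_run_")) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    synth = list(
      duration_s = 360,
      bout_rate = 12,
      n_per_type = 12,
      types = c("E1", "E2", "I1", "I2", "I3", "I4", "O", "NR"),
      baseline_rate = 5,
      isi_mean = 0.366,
      isi_sd = 0.064,
      flat_fraction = 0.5
    ),
    segmentation = list(
      enabled = TRUE,
      snippet_s = 4,
      sample_rate = 250e3,
      noise_sd = 0.05,
      threshold_sd = 3,
      min_dur = 0.005,
      min_gap = 0.020
    ),
    response = list(alpha = 0.05),
    classification = list(
      enabled = TRUE,
      perplexity = 30,
      grid_size = 100,
      sigma_bins = 2,
      tolerance_frac = 0.2,
      delta = 0.05
    ),
    tagging = list(
      enabled = TRUE,
      n_tagged = 5,
      n_untagged = 5,
      background_rate = 5,
      reliability = 0.8,
      latency_mean = 3,
      latency_jitter_sd = 1
    )
  ), class = "run_config")
}

validate_config <- function(config) {
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config must declare a numeric `seed`")
  if (is.null(config$out_dir)) stop("config must declare `out_dir`")
  required <- c("synth", "segmentation", "response", "classification",
                "tagging")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing stages: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Run the end-to-end pipeline on a synthetic session
#'
#' Synthesizes a USV session with planted response types, optionally
#' exercises the audio segmenter on a short rendered snippet, computes every
#' unit's response profile, discovers response types (when enough units are
#' responsive), simulates and classifies tagging sessions, and assembles a
#' counts-by-area table with the associated contingency statistics. All
#' tables are written as CSV/JSON under `config$out_dir` together with the
#' round-tripped configuration and a run log; outputs are a pure function of
#' the configuration, so a rerun with the same config is byte-identical.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, a list with the main in-memory results (`usv`, `units`,
#'   `profiles`, `typing`, `tags`, `counts`, `stats`, `out_dir`).
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain, file.path(config$out_dir, "config.yaml"))

  # --- synthesis -----------------------------------------------------------
  sy <- config$synth
  usv <- gen_usv_stream(sy$duration_s, bout_rate = sy$bout_rate,
                        isi_mean = sy$isi_mean, isi_sd = sy$isi_sd,
                        flat_fraction = sy$flat_fraction,
                        seed = config$seed)
  types <- rep(sy$types, each = sy$n_per_type)
  pop <- gen_population(types, usv, sy$duration_s,
                        baseline_rate = sy$baseline_rate,
                        seed = config$seed + 1)
  say("synth: ", nrow(usv), " syllables in ", max(usv$bout_id), " bouts; ",
      length(types), " units")
  write.csv(usv, file.path(config$out_dir, "syllables.csv"),
            row.names = FALSE)
  spikes_df <- data.frame(
    unit_id = rep(pop$units$unit_id, lengths(pop$spikes)),
    time_s = unlist(pop$spikes))
  write.csv(spikes_df, file.path(config$out_dir, "spikes.csv"),
            row.names = FALSE)

  # --- segmentation demo on a short snippet --------------------------------
  seg_tab <- NULL
  if (isTRUE(config$segmentation$enabled)) {
    sg <- config$segmentation
    snip <- usv[usv$onset_s < sg$snippet_s & usv$offset_s < sg$snippet_s, ]
    wav <- gen_audio(snip, sample_rate = sg$sample_rate,
                     duration = sg$snippet_s, noise_sd = sg$noise_sd,
                     seed = config$seed + 2)
    seg_tab <- segment_audio(wav, threshold_sd = sg$threshold_sd,
                             min_dur = sg$min_dur, min_gap = sg$min_gap)
    say("segmentation: ", nrow(seg_tab), " of ", nrow(snip),
        " planted syllables detected in a ", sg$snippet_s, " s snippet")
    write.csv(seg_tab, file.path(config$out_dir, "segmented_snippet.csv"),
              row.names = FALSE)
  }

  # --- response profiles ---------------------------------------------------
  profiles <- lapply(pop$spikes, unit_response_profile, usv = usv,
                     alpha = config$response$alpha)
  units <- pop$units
  units$responsive <- vapply(profiles, function(p) p$responsive, logical(1))
  units$baseline_rate_hat <- vapply(profiles, function(p) p$baseline_rate,
                                    numeric(1))
  say("responses: ", sum(units$responsive, na.rm = TRUE), " of ",
      nrow(units), " units responsive")

  # --- type discovery ------------------------------------------------------
  typing <- NULL
  resp_idx <- which(!is.na(units$responsive) & units$responsive)
  units$type <- ifelse(is.na(units$responsive), NA_character_, "NR")
  min_units <- 3 * config$classification$perplexity + 1
  if (isTRUE(config$classification$enabled) &&
      length(resp_idx) >= min_units) {
    V <- do.call(rbind, lapply(profiles[resp_idx], `[[`, "vector25"))
    cl <- config$classification
    typing <- classify_response_types(
      V, units$baseline_rate_hat[resp_idx], perplexity = cl$perplexity,
      seed = config$seed + 3, grid_size = cl$grid_size,
      sigma_bins = cl$sigma_bins, tolerance_frac = cl$tolerance_frac,
      delta = cl$delta)
    units$type[resp_idx] <- typing$type
    say("classification: ", length(unique(typing$labels)),
        " clusters over ", length(resp_idx), " responsive units")
    vec_out <- cbind(unit_id = units$unit_id[resp_idx], as.data.frame(V))
    write.csv(vec_out, file.path(config$out_dir, "response_vectors.csv"),
              row.names = FALSE)
  } else if (isTRUE(config$classification$enabled)) {
    say("classification: skipped (", length(resp_idx),
        " responsive units < ", min_units, " required for the embedding)")
  }
  write.csv(units, file.path(config$out_dir, "units.csv"),
            row.names = FALSE)

  # --- optogenetic tagging -------------------------------------------------
  tags <- NULL
  if (isTRUE(config$tagging$enabled)) {
    tg <- config$tagging
    spec <- tagging_spec(latency_mean = tg$latency_mean,
                         latency_jitter_sd = tg$latency_jitter_sd,
                         reliability = tg$reliability)
    tagged_flag <- rep(c(TRUE, FALSE), c(tg$n_tagged, tg$n_untagged))
    tags <- do.call(rbind, lapply(seq_along(tagged_flag), function(i) {
      s <- gen_tagging_session(spec, background_rate = tg$background_rate,
                               tagged = tagged_flag[i],
                               seed = config$seed + 10 + i)
      r <- classify_tag(s)
      data.frame(session = i, tagged = tagged_flag[i],
                 salt_p = r$salt_p, salt_info = r$salt_info,
                 waveform_r = r$waveform_r, rate_ratio = r$rate_ratio,
                 light_responsive = r$light_responsive)
    }))
    say("tagging: ", sum(tags$light_responsive[tags$tagged]), "/",
        tg$n_tagged, " tagged and ",
        sum(tags$light_responsive[!tags$tagged]), "/", tg$n_untagged,
        " untagged units flagged light-responsive")
    write.csv(tags, file.path(config$out_dir, "tag_results.csv"),
              row.names = FALSE)
  }

  # --- group statistics ----------------------------------------------------
  labeled <- !is.na(units$type)
  part <- assign_part(units$ap_mm)
  region_part <- paste0(units$region, "-",
                        ifelse(part == "anterior", "A", "P"))
  counts <- build_count_table(units$type[labeled], region_part[labeled])
  write.csv(cbind(data.frame(area = rownames(counts)), as.data.frame(counts),
                  Total = attr(counts, "total")),
            file.path(config$out_dir, "count_table.csv"), row.names = FALSE)
  stats_out <- list()
  if (all(c("M1-A", "M1-P", "M2-A", "M2-P") %in% rownames(counts))) {
    tabs <- region_contrast_tables(counts)
    stats_out <- lapply(tabs, function(tb) {
      ci <- odds_ratio_ci(tb)
      list(table = unname(tb), fisher_p = fisher_exact_p(tb),
           odds_ratio = ci$or, ci_lower = ci$lower, ci_upper = ci$upper)
    })
    say("stats: ", length(stats_out), " region contrasts computed")
  }
  jsonlite::write_json(stats_out, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(usv = usv, units = units, profiles = profiles,
                 typing = typing, tags = tags, segmented = seg_tab,
                 counts = counts, stats = stats_out,
                 out_dir = config$out_dir))
}
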