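#' Default pipeline configuration
#'
#' Flat key-value settings shared by the per-species pipeline and the
#' cross-species comparison:
#' \describe{
#'   \item{mode}{`"mrna"` (100-base anchors) or `"reads"` (80-base anchors,
#'     the convention for fragmented short reads).}
#'   \item{anchor_len}{Anchor length; `NA` means derive from `mode`.}
#'   \item{min_tail}{Minimum poly(A) tail length (12).}
#'   \item{cor_includes_site}{Shift the COR window from +1..+100 to 0..+99.}
#'   \item{exclude_ip_sites}{Drop internal-priming-flagged sites before
#'     profiling (default `FALSE`: sites are flagged, never silently
#'     dropped; exclusion is a reporting-level choice).}
#'   \item{min_sites}{Minimum unique sites below which a species is marked
#'     excluded rather than analysed (100).}
#'   \item{symmetrize_background}{Strand-symmetric genome background.}
#'   \item{id_exclude_pattern}{Regex of transcript ids to drop (e.g.
#'     predicted-mRNA accession prefixes); empty = no filter.}
#' }
#'
#' @param ... Overrides of the defaults.
#' @return Named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "mrna",
    anchor_len = NA_integer_,
    min_tail = 12L,
    cor_includes_site = FALSE,
    exclude_ip_sites = FALSE,
    min_sites = 100L,
    symmetrize_background = FALSE,
    id_exclude_pattern = ""
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  if (is.na(cfg$anchor_len)) {
    cfg$anchor_len <- if (cfg$mode == "reads") 80L else 100L
  }
  cfg
}

#' Read a flat key-value config file
#'
#' YAML-compatible `key: value` pairs; unknown keys are rejected so typos
#' fail loudly.
#'
#' @param path Path to the config file.
#' @return Named list of settings merged over [default_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(default_config, vals)
}

#' Run the per-species pipeline
#'
#' Executes screen -> map -> dedupe -> flag -> profile -> window
#' compositions -> region/genome ratios for one species. A species whose
#' unique-site count falls below `config$min_sites` is marked excluded (with
#' a warning) rather than errored, and carries no composition results.
#'
#' @param genome A `genome_store`, FASTA path, or named character vector.
#' @param transcripts Named character vector of transcript/read sequences,
#'   or a FASTA path.
#' @param config Settings from [default_config()] / [read_config()].
#' @param species_id,group Labels for cross-species comparison.
#' @return Object of class `species_run`: list with `species_id`, `group`,
#'   `config`, `screen` (report counts), `map` (mapping counts), `sites`
#'   (unique site table), `summary` (stage counts), `excluded`, and — unless
#'   excluded — `profile`, `windows` (named `base_composition` list:
#'   UTR100/COR100/DISTAL50/SIXBASE), `genome_comp`, `ratios` (named
#'   `ratio_table` list: UTR100/COR100), `ua_distal` (U/A ratio of the
#'   distal window), `n_ip`.
#' @export
run_species <- function(genome, transcripts, config = default_config(),
                        species_id = "species", group = NA_character_) {
  if (!inherits(genome, "genome_store")) genome <- genome_store(genome)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts)) && file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  scr <- screen_transcripts(
    transcripts, min_tail = config$min_tail, anchor_len = config$anchor_len,
    id_exclude_pattern = if (nzchar(config$id_exclude_pattern)) config$id_exclude_pattern else NULL
  )
  mp <- map_anchors(scr$anchors, genome, ip_min_run = config$min_tail)
  sites <- mp$sites
  n_ip <- sum(sites$ip_flag)
  analysis_sites <- if (isTRUE(config$exclude_ip_sites)) {
    sites[!sites$ip_flag, , drop = FALSE]
  } else {
    sites
  }

  summary <- c(
    n_input = unname(scr$report[["n_input"]]),
    n_tailed = unname(scr$report[["n_tailed"]]),
    n_unique_anchors = unname(scr$report[["n_unique_anchors"]]),
    n_mapped = mp$n_mapped_anchors,
    n_unique_sites = nrow(sites),
    n_ip_flagged = n_ip
  )
  if (!check_stage_monotonicity(summary)) {
    stop("internal error: stage counts not monotone non-increasing: ",
         paste(summary, collapse = " "), call. = FALSE)
  }
  run <- list(species_id = species_id, group = group, config = config,
              screen = scr$report, map = mp, sites = sites,
              summary = summary, n_ip = n_ip)

  if (nrow(analysis_sites) < config$min_sites) {
    warning("species '", species_id, "' excluded: ", nrow(analysis_sites),
            " unique site(s) < min_sites = ", config$min_sites, call. = FALSE)
    run$excluded <- TRUE
    class(run) <- "species_run"
    return(run)
  }
  run$excluded <- FALSE

  profile <- positional_profile(analysis_sites)
  ## in read mode (80-base anchors) the UTR window is the 80 available bases
  ## and the distal window does not exist
  specs <- lapply(
    stats::setNames(nm = c("UTR100", "COR100", "DISTAL50", "SIXBASE")),
    window_spec, cor_includes_site = config$cor_includes_site
  )
  specs$UTR100$lo <- max(specs$UTR100$lo, -profile$utr_len)
  if (profile$utr_len < 100L) specs$DISTAL50 <- NULL
  windows <- lapply(specs, window_composition, profile = profile)
  genome_comp <- genome_composition(
    genome, symmetrize = isTRUE(config$symmetrize_background))
  ratios <- list(
    UTR100 = region_genome_ratio(windows$UTR100, genome_comp,
                                 region_name = "UTR100", species_id = species_id),
    COR100 = region_genome_ratio(windows$COR100, genome_comp,
                                 region_name = "COR100", species_id = species_id)
  )
  run$profile <- profile
  run$windows <- windows
  run$genome_comp <- genome_comp
  run$ratios <- ratios
  run$ua_distal <- if (is.null(windows$DISTAL50)) NA_real_ else ua_ratio(windows$DISTAL50)
  class(run) <- "species_run"
  run
}

#' @export
print.species_run <- function(x, ...) {
  cat("species_run:", x$species_id,
      if (!is.na(x$group)) paste0("(", x$group, ")"), "\n")
  print(x$summary)
  if (isTRUE(x$excluded)) cat("** excluded: too few unique sites **\n")
  invisible(x)
}

## stage counts must shrink monotonically along the pipeline
check_stage_monotonicity <- function(summary) {
  s <- summary[c("n_input", "n_tailed", "n_unique_anchors", "n_mapped",
                 "n_unique_sites")]
  all(diff(s) <= 0)
}

#' Cross-species group comparison of U contents and ratios
#'
#' Builds the species-level samples the group tests run on — per-species U
#' contents of the 3'UTR window, the 3'COR window and the genome, and the
#' per-species region/genome U ratios — and applies one-way ANOVA plus
#' Duncan's letter display across region-by-group units, with an optional
#' equal-variance t-test on distal-window U/A ratios between two
#' super-groups (e.g. plants vs animals). Group summaries are unweighted
#' means over species, never site-count-weighted: the experimental unit is
#' the species.
#'
#' @param runs List of non-excluded `species_run` objects with `group` set.
#' @param supergroups Optional named character vector mapping group label ->
#'   super-group label; when it resolves to exactly 2 super-groups the U/A
#'   t-test is run.
#' @param alpha Significance level for the Duncan display (0.05).
#' @return Object of class `group_comparison`: list with `species` (the
#'   per-species table), `u_content` (anova + duncan over region_group units
#'   of U content), `u_ratio` (same over region/genome U ratios), and
#'   optionally `ua_t_test`.
#' @export
compare_groups <- function(runs, supergroups = NULL, alpha = 0.05) {
  runs <- Filter(function(r) !isTRUE(r$excluded), runs)
  if (length(runs) < 4L) {
    stop("need at least 2 groups with at least 2 species each; got ",
         length(runs), " usable species run(s)", call. = FALSE)
  }
  species <- do.call(rbind, lapply(runs, function(r) {
    data.frame(
      species_id = r$species_id, group = r$group,
      u_utr = r$windows$UTR100$pct[["TU"]],
      u_cor = r$windows$COR100$pct[["TU"]],
      u_genome = r$genome_comp$pct[["TU"]],
      ratio_utr = r$ratios$UTR100$ratio[["TU"]],
      ratio_cor = r$ratios$COR100$ratio[["TU"]],
      ua_distal = r$ua_distal,
      n_sites = unname(r$summary[["n_unique_sites"]]),
      stringsAsFactors = FALSE
    )
  }))
  tab_groups <- table(species$group)
  if (length(tab_groups) < 2L || any(tab_groups < 2L)) {
    stop("need at least 2 groups with at least 2 species each", call. = FALSE)
  }

  u_samples <- c(
    split(species$u_utr, paste0("UTR100_", species$group)),
    split(species$u_cor, paste0("COR100_", species$group)),
    split(species$u_genome, paste0("Genome_", species$group))
  )
  ratio_samples <- c(
    split(species$ratio_utr, paste0("UTR100_", species$group)),
    split(species$ratio_cor, paste0("COR100_", species$group))
  )
  out <- list(
    species = species,
    u_content = list(anova = anova_oneway(u_samples),
                     duncan = duncan_mrt(u_samples, alpha = alpha)),
    u_ratio = list(anova = anova_oneway(ratio_samples),
                   duncan = duncan_mrt(ratio_samples, alpha = alpha))
  )
  if (!is.null(supergroups)) {
    sg <- supergroups[species$group]
    lev <- unique(sg)
    if (length(lev) == 2L) {
      out$ua_t_test <- t_test_equal_var(species$ua_distal[sg == lev[1L]],
                                        species$ua_distal[sg == lev[2L]])
      out$ua_t_test$levels <- lev
    }
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison over", nrow(x$species), "species\n\n")
  cat("U content by region_group:\n")
  print(x$u_content$duncan)
  cat("\nRegion/genome U ratio by region_group:\n")
  print(x$u_ratio$duncan)
  if (!is.null(x$ua_t_test)) {
    cat(sprintf("\nDistal-window U/A ratio, %s vs %s: t = %.3f, df = %d, p = %.2g\n",
                x$ua_t_test$levels[1L], x$ua_t_test$levels[2L],
                x$ua_t_test$t, x$ua_t_test$df, x$ua_t_test$p))
  }
  invisible(x)
}

#' Write a group comparison as TSV + JSON
#'
#' Emits the Duncan letter tables (one TSV per response) and a
#' machine-readable JSON bundle of every test output.
#'
#' @param comparison A `group_comparison`.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    u_content = file.path(dir, "u_content_duncan.tsv"),
    u_ratio = file.path(dir, "u_ratio_duncan.tsv"),
    species = file.path(dir, "species_values.tsv"),
    json = file.path(dir, "comparison.json")
  )
  utils::write.table(comparison$u_content$duncan$table, paths[["u_content"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparison$u_ratio$duncan$table, paths[["u_ratio"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparison$species, paths[["species"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    u_content = list(anova = comparison$u_content$anova[c("F", "p", "mse")],
                     duncan = comparison$u_content$duncan$table),
    u_ratio = list(anova = comparison$u_ratio$anova[c("F", "p", "mse")],
                   duncan = comparison$u_ratio$duncan$table)
  )
  if (!is.null(comparison$ua_t_test)) {
    payload$ua_t_test <- comparison$ua_t_test[c("t", "df", "p", "levels")]
  }
  jsonlite::write_json(payload, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
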