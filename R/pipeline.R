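#' Load and validate a species table
#'
#' Reads the standard species CSV (columns `species, previous_name,
#' molecular, morphology, areas, elev_mean, elev_low, elev_high`) and
#' validates every record: unique species names, area strings restricted to
#' the configured letters with no duplicates, and elevational ordering
#' `elev_low <= elev_mean <= elev_high`. Validation errors name the
#' offending row.
#'
#' @param path CSV file path, or a data frame already in the schema.
#' @param areas The [area_system()] the area strings must come from.
#' @param quiet Suppress the summary message (default `FALSE`).
#' @return Tibble of validated records, row order preserved.
#' @export
load_species_table <- function(path, areas = area_system(), quiet = FALSE) {
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  needed <- c("species", "previous_name", "molecular", "morphology",
              "areas", "elev_mean", "elev_low", "elev_high")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("species table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[needed]
  df$previous_name <- as.character(df$previous_name)
  df$molecular <- as.logical(df$molecular)
  df$morphology <- as.logical(df$morphology)
  dup <- which(duplicated(df$species))
  if (length(dup) > 0L) {
    stop("duplicate species '", df$species[dup[1]], "' at row ", dup[1],
         call. = FALSE)
  }
  labs <- unclass(areas)
  for (i in seq_len(nrow(df))) {
    a <- df$areas[i]
    if (is.na(a) || !nzchar(a)) stop("empty area string at row ", i, call. = FALSE)
    ch <- strsplit(a, "")[[1]]
    unknown <- setdiff(ch, labs)
    if (length(unknown) > 0L) {
      stop("unknown area ", paste(unknown, collapse = ""), " at row ", i,
           call. = FALSE)
    }
    if (anyDuplicated(ch)) stop("duplicated area letter at row ", i, call. = FALSE)
    if (anyNA(c(df$elev_low[i], df$elev_mean[i], df$elev_high[i]))) {
      stop("missing elevational value at row ", i, call. = FALSE)
    }
    if (df$elev_low[i] > df$elev_mean[i] || df$elev_mean[i] > df$elev_high[i]) {
      stop("elevational ordering violated at row ", i,
           " (need low <= mean <= high)", call. = FALSE)
    }
  }
  if (!quiet) {
    message(sprintf("species table: %d species (%d with molecular, %d with morphological data)",
                    nrow(df), sum(df$molecular, na.rm = TRUE),
                    sum(df$morphology, na.rm = TRUE)))
  }
  df
}

#' Path to the packaged species table
#'
#' The packaged fixture transcribing the published species list of the
#' butterfly genus *Pteronymia* (53 species with data-availability flags,
#' biogeographic area strings over the nine Neotropical areas, and
#' elevational mean and 95%-range boundaries in metres).
#'
#' @return File path inside the installed package.
#' @export
species_table_path <- function() {
  system.file("extdata", "pteronymia_species.csv", package = "chronodiv",
              mustWork = TRUE)
}

#' Per-area species richness
#'
#' A species occupying several areas is counted once in each.
#'
#' @param records Validated species table (see [load_species_table()]).
#' @inheritParams load_species_table
#' @return Tibble `area`, `name`, `n_species`.
#' @export
area_richness <- function(records, areas = area_system()) {
  labs <- unclass(areas)
  counts <- vapply(labs, function(a) {
    if (nrow(records) == 0L) 0L else sum(grepl(a, records$areas, fixed = TRUE))
  }, integer(1))
  tibble::tibble(area = labs, name = names(areas), n_species = unname(counts))
}

#' Uniform calibration priors from host-plant lineage ages
#'
#' For herbivores whose diversification cannot predate their host plants,
#' each host lineage age provides a maximum age constraint: the prior on the
#' corresponding consumer clade is uniform between 0 (present) and the upper
#' boundary of the 95% credibility interval of the host lineage age.
#'
#' @param host_plant_ages Data frame with columns `label`, `median`,
#'   `ci_low`, `ci_high` (ages in my).
#' @return Tibble of priors: `clade`, `kind` (`"uniform"`), `lower` (0),
#'   `upper` (my).
#' @export
build_calibration_priors <- function(host_plant_ages) {
  df <- tibble::as_tibble(host_plant_ages)
  needed <- c("label", "median", "ci_low", "ci_high")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$ci_low) || anyNA(df$ci_high)) {
    stop("missing credibility interval", call. = FALSE)
  }
  bad <- which(df$ci_low > df$median | df$median > df$ci_high)
  if (length(bad) > 0L) {
    stop("inverted credibility interval for '", df$label[bad[1]], "'",
         call. = FALSE)
  }
  tibble::tibble(clade = df$label, kind = "uniform", lower = 0,
                 upper = df$ci_high)
}

#' Run the full analysis pipeline on a tree and species table
#'
#' Orchestrates the three inference stages on one chronogram: (i) DEC
#' biogeography (ML rates, ancestral ranges, in-situ speciation fraction and
#' colonization counts), (ii) lambda/delta trait evolution for the
#' elevational mean and both 95%-range boundaries, (iii) the six
#' time-dependent diversification models with AIC ranking and the
#' rate-through-time curve of the best model. Report tables are written as
#' TSV together with a manifest (config hash, seed, package version);
#' identical inputs and seed give byte-identical outputs.
#'
#' @param config List with elements `tree` (Newick path or `phylo`),
#'   `species` (CSV path or data frame), and optionally `schedule`
#'   (a [dispersal_schedule()]), `stages` (subset of
#'   `c("dec", "traits", "div")`), `max_range_size`, `focal_areas`
#'   (in-situ region, default `"C"`), `colonization_targets` (default
#'   `c("A", "D")`), `f`, `seed`, `out_dir`.
#' @return Invisible list of the report tibbles (also written to
#'   `config[["out_dir"]]` when given).
#' @export
run_pipeline <- function(config) {
  stages <- config[["stages"]] %||% c("dec", "traits", "div")
  seed <- config[["seed"]] %||% 1L
  # fail fast: every stage input must exist before any stage runs
  if (is.null(config[["tree"]])) stop("config$tree is required", call. = FALSE)
  if (is.null(config[["species"]])) stop("config$species is required", call. = FALSE)
  if (is.character(config[["tree"]]) && !file.exists(config[["tree"]])) {
    stop("tree file not found: ", config[["tree"]], call. = FALSE)
  }
  if (is.character(config[["species"]]) && !file.exists(config[["species"]])) {
    stop("species file not found: ", config[["species"]], call. = FALSE)
  }
  tree <- if (inherits(config[["tree"]], "phylo")) config[["tree"]] else
    parse_newick(paste(readLines(config[["tree"]], warn = FALSE), collapse = ""))
  species <- load_species_table(config[["species"]], quiet = TRUE)
  missing_tips <- setdiff(tree$tip.label, species$species)
  if (length(missing_tips) > 0L) {
    stop("species table lacks tree tips: ",
         paste(utils::head(missing_tips, 5), collapse = ", "), call. = FALSE)
  }
  schedule <- config[["schedule"]] %||% default_dispersal_schedule()
  max_range_size <- config[["max_range_size"]] %||% 4L
  focal <- config[["focal_areas"]] %||% "C"
  col_targets <- config[["colonization_targets"]] %||% c("A", "D")
  f <- config[["f"]] %||% 1
  out <- list()

  if ("dec" %in% stages) {
    ranges <- stats::setNames(species$areas, species$species)[tree$tip.label]
    dec <- fit_dec(tree, ranges, schedule = schedule,
                   max_range_size = max_range_size, seed = seed)
    anc <- dec$ancestral
    node_tab <- dplyr::select(anc, "node", "label", "is_tip", "age",
                              "mp_state", "mp_prob", "top3")
    insitu <- count_in_situ_speciation(dec, focal_areas = focal,
                                       areas = schedule$areas)
    colon <- purrr::map_dfr(col_targets, function(a) {
      ev <- count_colonizations(dec, target_area = a, areas = schedule$areas)
      dplyr::mutate(ev, target = a, .before = 1L)
    })
    out$dec <- list(fit = dec, nodes = node_tab, in_situ = insitu,
                    colonizations = colon)
  }

  if ("traits" %in% stages) {
    traits <- list(
      mean = stats::setNames(species$elev_mean, species$species),
      lower = stats::setNames(species$elev_low, species$species),
      upper = stats::setNames(species$elev_high, species$species)
    )
    fits <- purrr::imap(traits, function(v, nm) {
      fit_trait_model(tree, v[tree$tip.label], seed = seed, trait_name = nm)
    })
    report <- purrr::map_dfr(fits, function(ft) {
      tibble::tibble(
        trait = ft$trait_name,
        lambda = ft$lambda, delta = ft$delta,
        lrt_delta = ft$lrt_delta$statistic, p_delta = round(ft$lrt_delta$p_value, 3),
        lrt_lambda = ft$lrt_lambda$statistic, p_lambda = round(ft$lrt_lambda$p_value, 3)
      )
    })
    recon <- purrr::imap(fits, function(ft, nm) {
      rescale_and_reconstruct(tree, traits[[nm]][tree$tip.label], ft)
    })
    out$traits <- list(fits = fits, report = report, reconstructions = recon)
  }

  if ("div" %in% stages) {
    div <- fit_bd_models(tree, f = f, seed = seed)
    rtt <- rate_through_time(div)
    out$div <- list(fit = div, table = div$table, rate_curve = rtt)
  }

  if (!is.null(config[["out_dir"]])) {
    dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) readr::write_tsv(x, file.path(config[["out_dir"]], f),
                                          progress = FALSE)
    if (!is.null(out$dec)) {
      wt(out$dec$nodes, "dec_nodes.tsv")
      wt(out$dec$in_situ, "dec_in_situ.tsv")
      wt(out$dec$colonizations, "dec_colonizations.tsv")
    }
    if (!is.null(out$traits)) wt(out$traits$report, "trait_report.tsv")
    if (!is.null(out$div)) {
      wt(out$div$table, "div_models.tsv")
      wt(tibble::as_tibble(out$div$rate_curve), "rate_through_time.tsv")
    }
    cfg_for_hash <- config[setdiff(names(config), "out_dir")]
    manifest <- list(
      package = "chronodiv",
      version = as.character(utils::packageVersion("chronodiv")),
      seed = seed,
      stages = stages,
      config_hash = rlang::hash(cfg_for_hash)
    )
    yaml::write_yaml(manifest, file.path(config[["out_dir"]], "manifest.yml"))
  }
  invisible(out)
}
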