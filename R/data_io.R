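#' @title Survey, recruitment, and fecundity tables
#'
#' @description
#' The package works on three flat tables, all UTF-8 comma-separated files
#' with one header row:
#'
#' * **survey** — one row per tagged colony per annual transition:
#'   `colony_id, region, site, taxon, strategy, year_t, size_t, survived,
#'   size_t1, fragmented, remnant_sizes`. Sizes are horizontal surface areas
#'   in cm2 on the raw scale; `remnant_sizes` is a semicolon-delimited list of
#'   remnant areas (empty when no fragmentation occurred). A colony followed
#'   over several transitions contributes several rows sharing `colony_id`.
#' * **recruits** — one row per region, site, and survey year:
#'   `region, site, year, n_new, new_sizes`, counting all newly appearing
#'   colonies under 5 cm diameter with their areas.
#' * **fecundity** — one row per colony-level larval-output measurement:
#'   `strategy, colony_size, larval_output`.
#'
#' Log transformation of sizes (natural log) happens inside the fitting
#' functions; files always hold raw cm2 areas.
#'
#' @name survey-tables
NULL

survey_columns <- c("colony_id", "region", "site", "taxon", "strategy",
                    "year_t", "size_t", "survived", "size_t1", "fragmented",
                    "remnant_sizes")

#' Validate a colony-observation table
#'
#' Checks the row-level invariants of the survey table: positive sizes,
#' no size at t+1 or fragmentation for dead colonies, and at least one
#' positive remnant size whenever fragmentation is recorded.
#'
#' @param obs A data frame of colony observations (see [survey-tables]).
#' @return `obs` invisibly; offending rows raise an error listing row numbers.
#' @export
validate_survey <- function(obs) {
  missing_cols <- setdiff(setdiff(survey_columns, "remnant_sizes"),
                          names(obs))
  if (length(missing_cols) > 0) {
    stop("survey table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.list(obs$remnant_sizes)) {
    obs$remnant_sizes <- unpack_sizes(as.character(obs$remnant_sizes))
  }
  bad <- function(cond) which(cond %in% TRUE)
  problems <- list(
    "non-positive size_t" = bad(!(obs$size_t > 0)),
    "size_t1 present for non-survivor" =
      bad(!obs$survived & !is.na(obs$size_t1)),
    "fragmentation recorded for non-survivor" =
      bad(!obs$survived & obs$fragmented),
    "non-positive size_t1" = bad(obs$survived & !is.na(obs$size_t1) &
                                   obs$size_t1 <= 0),
    "fragmented but no remnant sizes" =
      bad(obs$fragmented & lengths(obs$remnant_sizes) == 0),
    "non-positive remnant size" =
      bad(vapply(obs$remnant_sizes, function(v) any(v <= 0), logical(1)))
  )
  problems <- problems[lengths(problems) > 0]
  if (length(problems) > 0) {
    msg <- paste(vapply(seq_along(problems), function(i) {
      paste0(names(problems)[i], " in row(s) ",
             paste(utils::head(problems[[i]], 10), collapse = ", "))
    }, character(1)), collapse = "; ")
    stop("survey validation failed: ", msg)
  }
  invisible(obs)
}

#' Read a colony survey table
#'
#' @param path Path to a survey CSV (see [survey-tables] for the dialect).
#' @return A data frame of colony observations with `remnant_sizes` as a
#'   list-column of numeric vectors.
#' @export
read_survey <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(survey_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("survey file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$survived <- as.logical(raw$survived)
  raw$fragmented <- as.logical(raw$fragmented)
  raw$year_t <- as.integer(raw$year_t)
  raw$size_t <- as.numeric(raw$size_t)
  st1 <- as.character(raw$size_t1)
  st1[!nzchar(st1)] <- NA_character_
  raw$size_t1 <- as.numeric(st1)
  raw$remnant_sizes <- unpack_sizes(as.character(raw$remnant_sizes))
  validate_survey(raw)
  raw
}

#' Write a colony survey table
#'
#' @param obs Colony-observation data frame.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_survey <- function(obs, path) {
  validate_survey(obs)
  out <- obs[survey_columns]
  out$remnant_sizes <- pack_sizes(obs$remnant_sizes)
  out$size_t <- format(out$size_t, digits = 10, trim = TRUE,
                       scientific = FALSE)
  out$size_t1 <- ifelse(is.na(obs$size_t1), NA,
                        format(obs$size_t1, digits = 10, trim = TRUE,
                               scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write an annual recruit-survey table
#'
#' @param path CSV path with columns `region, site, year, n_new, new_sizes`.
#' @return A data frame with `new_sizes` as a list-column; `n_new` must equal
#'   the number of listed sizes.
#' @export
read_recruits <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "site", "year", "n_new", "new_sizes")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("recruit file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$year <- as.integer(raw$year)
  raw$n_new <- as.integer(raw$n_new)
  raw$new_sizes <- unpack_sizes(as.character(raw$new_sizes))
  bad <- which(lengths(raw$new_sizes) != raw$n_new)
  if (length(bad) > 0) {
    stop("n_new does not match listed sizes in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  raw
}

#' @rdname read_recruits
#' @param recruits Recruit-survey data frame.
#' @export
write_recruits <- function(recruits, path) {
  out <- recruits[c("region", "site", "year", "n_new")]
  out$new_sizes <- pack_sizes(recruits$new_sizes)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a colony-size vs larval-output table
#'
#' @param path CSV path with columns `strategy, colony_size, larval_output`.
#' @return A data frame; colony sizes must be positive, larval outputs
#'   non-negative.
#' @export
read_fecundity <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strategy", "colony_size", "larval_output")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("fecundity file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(raw$colony_size <= 0)) {
    stop("non-positive colony_size in row(s) ",
         paste(utils::head(which(raw$colony_size <= 0), 10), collapse = ", "))
  }
  if (any(raw$larval_output < 0)) {
    stop("negative larval_output in row(s) ",
         paste(utils::head(which(raw$larval_output < 0), 10), collapse = ", "))
  }
  raw
}

#' @rdname read_fecundity
#' @param fec Fecundity data frame.
#' @export
write_fecundity <- function(fec, path) {
  utils::write.csv(fec[c("strategy", "colony_size", "larval_output")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a genus-to-strategy catalog
#'
#' The catalog maps each taxon (genus) to one or more life-history
#' strategies. A taxon whose local species pool spans several strategies has
#' several rows with the local species count per strategy.
#'
#' @param path CSV path with columns `taxon, strategy, n_species`.
#' @return A data frame usable by [assign_strategies()].
#' @export
read_strategy_catalog <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "strategy", "n_species")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("strategy catalog missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(raw$n_species <= 0 | raw$n_species != round(raw$n_species))) {
    stop("species counts must be positive integers")
  }
  raw
}

#' Assign life-history strategies to tagged colonies
#'
#' Colonies of a genus mapped to a single strategy receive it
#' deterministically. Colonies of a genus whose local species pool spans
#' several strategies are assigned randomly, with probabilities proportional
#' to the local species count per strategy. Assignment is per colony, not per
#' row: every transition row of one colony receives the same strategy, and
#' the outcome is reproducible under a fixed seed.
#'
#' @param obs Colony-observation data frame with a `taxon` column.
#' @param catalog Strategy catalog (see [read_strategy_catalog()]).
#' @param seed Integer seed controlling the random assignments.
#' @return `obs` with the `strategy` column resolved.
#' @export
assign_strategies <- function(obs, catalog, seed) {
  unknown <- setdiff(unique(obs$taxon), unique(catalog$taxon))
  if (length(unknown) > 0) {
    stop("taxon not present in strategy catalog: ",
         paste(unknown, collapse = ", "))
  }
  split_cat <- split(catalog, catalog$taxon)
  ids <- unique(obs$colony_id)
  id_taxon <- obs$taxon[match(ids, obs$colony_id)]
  assigned <- with_seed(seed, {
    vapply(seq_along(ids), function(i) {
      entry <- split_cat[[id_taxon[i]]]
      if (nrow(entry) == 1) {
        entry$strategy
      } else {
        sample(entry$strategy, 1, prob = entry$n_species)
      }
    }, character(1))
  })
  obs$strategy <- assigned[match(obs$colony_id, ids)]
  obs
}

#' Filter observations to one assemblage
#'
#' Subsets a mixed observation table to one life-history strategy and/or
#' region. Generalist colonies are excluded from analysis sets by default
#' because of their limited representation.
#'
#' @param obs Colony-observation data frame.
#' @param strategy Optional strategy to retain.
#' @param region Optional region to retain.
#' @param drop_generalists Drop colonies labelled `generalist` (default TRUE).
#' @return The matching subset; an empty result triggers a warning, not an
#'   error.
#' @export
filter_assemblage <- function(obs, strategy = NULL, region = NULL,
                              drop_generalists = TRUE) {
  keep <- rep(TRUE, nrow(obs))
  if (drop_generalists) keep <- keep & obs$strategy != "generalist"
  if (!is.null(strategy)) keep <- keep & obs$strategy == strategy
  if (!is.null(region)) keep <- keep & obs$region == region
  out <- obs[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("filter_assemblage: no observations match the requested subset")
  }
  rownames(out) <- NULL
  out
}
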