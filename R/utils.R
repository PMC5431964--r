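# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so generators never perturb a user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Exact-string species id normalisation: trim ends, collapse internal runs of
# whitespace. No fuzzy synonym resolution by design.
normalize_species_id <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

# Validate a cell table and clamp reserve_area to land_area (digitisation
# slivers where reserve polygons overhang a cell are common; clamp + warn
# rather than error).
validate_cells <- function(cells) {
  stopifnot(is.data.frame(cells))
  required <- c("cell_id", "land_area")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0L) {
    stop("cell table lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) {
    stop("cell_id values must be unique", call. = FALSE)
  }
  if (is.null(cells$reserve_area)) cells$reserve_area <- 0
  if (any(cells$land_area < 0) || any(cells$reserve_area < 0)) {
    stop("land_area and reserve_area must be non-negative", call. = FALSE)
  }
  over <- cells$reserve_area > cells$land_area
  if (any(over)) {
    warning(sum(over), " cell(s) had reserve_area > land_area; clamped to land_area",
            call. = FALSE)
    cells$reserve_area[over] <- cells$land_area[over]
  }
  cells
}

`%||%` <- function(a, b) if (is.null(a)) b else a
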