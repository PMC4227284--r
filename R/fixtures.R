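#' @keywords internal
#' @import data.table
"_PACKAGE"

.datatable.aware <- TRUE

# Package-local cache for parsed fixtures so repeated scoring calls do not
# re-read JSON from disk.
.wardscores_env <- new.env(parent = emptyenv())

#' Names of the supported severity scores
#'
#' @return Character vector of the nine scoring-system names.
#' @export
score_names <- function() {
  c("SOFA", "PIRO", "ViEWS", "SCS", "MEDS", "MEWS", "SAPS2", "APACHE2", "REMS")
}

.fixture_file <- function(name) {
  file <- switch(name,
    SOFA = "sofa.json", PIRO = "piro.json", ViEWS = "views.json",
    SCS = "scs.json", MEDS = "meds.json", MEWS = "mews.json",
    SAPS2 = "saps2.json", APACHE2 = "apache2.json", REMS = "rems.json",
    stop("unknown score name: ", name)
  )
  system.file("extdata", "scores", file, package = "wardscores", mustWork = TRUE)
}

.parse_bound <- function(x) {
  if (is.character(x)) {
    if (x == "inf") return(Inf)
    if (x == "-inf") return(-Inf)
    stop("unparseable band bound: ", x)
  }
  as.numeric(x)
}

#' Load one score definition from its shipped fixture
#'
#' Parses the JSON band-table fixture for one scoring system into a
#' `score_definition` object: a list of components, each carrying an ordered
#' table of half-open `[lo, hi)` bands mapping a physiologic value to integer
#' points, plus the score's special terms (boolean flag points and named
#' computation hooks) and its documented total range. The fixture is
#' validated on load: within each component the bands must partition the
#' plausible range with no gaps and no overlaps.
#'
#' @param name Score name, one of [score_names()].
#' @return An object of class `score_definition`.
#' @export
score_definition <- function(name) {
  name <- match.arg(name, score_names())
  key <- paste0("def_", name)
  if (!is.null(.wardscores_env[[key]])) return(.wardscores_env[[key]])
  raw <- jsonlite::read_json(.fixture_file(name))
  comps <- lapply(raw$components, function(cmp) {
    bands <- do.call(rbind, lapply(cmp$bands, function(b) {
      data.frame(lo = .parse_bound(b$lo), hi = .parse_bound(b$hi),
                 points = as.integer(b$points))
    }))
    bands <- bands[order(bands$lo), , drop = FALSE]
    rownames(bands) <- NULL
    if (any(bands$hi[-nrow(bands)] != bands$lo[-1])) {
      stop("fixture for ", raw$name, " component ", cmp$name,
           " has a gap or overlap in its band table")
    }
    list(name = cmp$name, unit = cmp$unit, direction = cmp$direction,
         bands = bands)
  })
  names(comps) <- vapply(comps, `[[`, "", "name")
  special <- lapply(raw$special_terms, function(s) {
    s$points <- if (!is.null(s$points)) as.integer(s$points) else NULL
    s
  })
  def <- structure(
    list(name = raw$name, version = raw$version, provenance = raw$provenance,
         total_range = c(.parse_bound(raw$total_range[[1]]),
                         .parse_bound(raw$total_range[[2]])),
         components = comps, special_terms = special),
    class = "score_definition"
  )
  .wardscores_env[[key]] <- def
  def
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s (v%s)\n", x$name, x$version))
  cat(sprintf("  components: %s\n", paste(names(x$components), collapse = ", ")))
  cat(sprintf("  special terms: %d; total range [%d, %d]\n",
              length(x$special_terms), x$total_range[1], x$total_range[2]))
  invisible(x)
}

#' Look up band points for a vector of values
#'
#' Vectorized lookup in a component's band table. Bands are half-open
#' `[lo, hi)`: a value equal to a cut-point belongs to the band whose `lo` it
#' equals. A value falling outside every band (possible only if the fixture
#' has a gap) is a configuration error, never silently clamped.
#'
#' @param bands Data frame with columns `lo`, `hi`, `points`, sorted by `lo`.
#' @param values Numeric vector.
#' @return Integer vector of points, same length as `values`.
#' @export
band_points <- function(bands, values) {
  if (any(is.na(values))) stop("band_points: NA value (impute before scoring)")
  idx <- findInterval(values, bands$lo)
  bad <- idx == 0L | values >= bands$hi[pmax(idx, 1L)]
  if (any(bad)) {
    stop(sprintf("value %s outside all bands [%s, %s): fixture gap",
                 values[which(bad)[1]], min(bands$lo), max(bands$hi)))
  }
  bands$points[idx]
}

#' Normal-value registry shared by imputation and simulation
#'
#' Reads the shipped normal-values fixture: one documented physiologic
#' midpoint per analyte (chosen to score 0 points in every system where such
#' a value exists) plus the spread, derangement direction and plausibility
#' bounds used by the synthetic cohort generator. A single file backs both
#' the assume-normal imputation rule and the generator's baselines so the
#' two can never drift apart.
#'
#' @return Named list of per-analyte entries with fields `unit`, `kind`,
#'   `mean`, `sd`, `derange`, `lo`, `hi`.
#' @export
normal_values <- function() {
  if (!is.null(.wardscores_env$normals)) return(.wardscores_env$normals)
  path <- system.file("extdata", "normals.json", package = "wardscores",
                      mustWork = TRUE)
  normals <- jsonlite::read_json(path)$analytes
  .wardscores_env$normals <- normals
  normals
}

#' Read a plain-text infection code list
#'
#' Reads a one-code-per-line text file (comments starting with `#` and
#' trailing labels after whitespace are ignored). The package ships a small
#' synthetic surrogate list at
#' `system.file("extdata", "infection_codes_synthetic.txt", package = "wardscores")`.
#'
#' @param path Path to the list file.
#' @return Character vector of codes.
#' @export
read_infection_codes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[[:space:]]+"), `[[`, "", 1L)
}
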