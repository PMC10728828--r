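# Synthetic slide cohorts and tile workloads.
#
# A cohort is a pair of tables: one row per case (organ, specimen type,
# number of slides) and one row per whole-slide image (WSI) carrying the
# quantities the emission model consumes: total pixel count, file size,
# and the fractions of the slide occupied by tissue and by a region of
# interest (ROI). Tile workloads are derived from these fractions rather
# than from spatial masks: no image data is involved anywhere.

#' Distribution specification for cohort generation
#'
#' A small tagged container naming a sampling distribution and its
#' parameters, used for every stochastic field of [cohort_config()].
#' Supported distributions: `"lognormal"` (`meanlog`, `sdlog`), `"beta"`
#' (`shape1`, `shape2`), `"uniform"` (`min`, `max`) and `"fixed"` (`value`).
#'
#' @param name Distribution name.
#' @param ... Named distribution parameters (all finite numbers).
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("lognormal", meanlog = log(20), sdlog = 0.5)
dist_spec <- function(name, ...) {
  params <- list(...)
  required <- switch(name,
    lognormal = c("meanlog", "sdlog"),
    beta      = c("shape1", "shape2"),
    uniform   = c("min", "max"),
    fixed     = "value",
    stop(sprintf("unknown distribution '%s' in distribution spec", name),
         call. = FALSE)
  )
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop(sprintf("configuration error in distribution spec '%s': missing parameter(s) %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- !vapply(params[required], function(p)
    is.numeric(p) && length(p) == 1L && is.finite(p), logical(1))
  if (any(bad)) {
    stop(sprintf("configuration error in distribution spec '%s': non-finite parameter(s) %s",
                 name, paste(required[bad], collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, params = params[required]), class = "dist_spec")
}

sample_dist <- function(spec, n) {
  p <- spec$params
  switch(spec$name,
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    beta      = stats::rbeta(n, p$shape1, p$shape2),
    uniform   = stats::runif(n, p$min, p$max),
    fixed     = rep(p$value, n)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of a two-organ (breast/prostate)
#' histopathology cohort: a handful of cases per organ, right-skewed slide
#' counts per case and pixel counts per slide, bounded tissue and ROI
#' fractions, and a concave pixels-to-bytes compression curve with
#' multiplicative noise tuned so that file size and pixel count show a
#' moderate Pearson correlation (default target r = 0.58).
#'
#' @param n_cases Named integer vector of cases per organ
#'   (default `c(prostate = 5, breast = 8)`).
#' @param slides_per_case,pixels_per_slide,tissue_fraction,roi_given_tissue
#'   [dist_spec()] objects. `roi_given_tissue` is sampled in \[0,1\] and
#'   multiplied by the slide's tissue fraction, which enforces
#'   `roi_fraction <= tissue_fraction`.
#' @param filesize_model List with `coef_a`, `exponent_b` (the concave map
#'   `bytes = a * pixels^b`) and `target_correlation`, the desired Pearson
#'   correlation between raw pixel count and file size; the log-normal noise
#'   level is solved analytically from the target.
#' @param seed Integer root seed; per-purpose child streams are derived
#'   from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = c(prostate = 5, breast = 8),
                          slides_per_case = dist_spec("lognormal",
                                                      meanlog = log(20), sdlog = 0.6),
                          pixels_per_slide = dist_spec("lognormal",
                                                       meanlog = log(1e9), sdlog = 0.5),
                          tissue_fraction = dist_spec("beta", shape1 = 2, shape2 = 2),
                          roi_given_tissue = dist_spec("beta", shape1 = 2, shape2 = 3),
                          filesize_model = list(coef_a = 30, exponent_b = 0.8,
                                                target_correlation = 0.58),
                          seed = 1L) {
  if (is.null(names(n_cases)) || any(!nzchar(names(n_cases)))) {
    stop("configuration error in field `n_cases`: must be a named vector of per-organ counts",
         call. = FALSE)
  }
  if (any(n_cases < 1) || any(n_cases != round(n_cases))) {
    stop("configuration error in field `n_cases`: counts must be positive integers",
         call. = FALSE)
  }
  for (f in c("slides_per_case", "pixels_per_slide", "tissue_fraction",
              "roi_given_tissue")) {
    if (!inherits(get(f), "dist_spec")) {
      stop(sprintf("configuration error in field `%s`: expected a dist_spec", f),
           call. = FALSE)
    }
  }
  r <- filesize_model$target_correlation
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0 || r >= 1) {
    stop("configuration error in field `filesize_model$target_correlation`: must be in (0, 1)",
         call. = FALSE)
  }
  assert_number(filesize_model$coef_a, "filesize_model$coef_a", lower = 1e-12)
  assert_number(filesize_model$exponent_b, "filesize_model$exponent_b", lower = 1e-12)
  assert_number(seed, "seed")
  structure(list(n_cases = n_cases,
                 slides_per_case = slides_per_case,
                 pixels_per_slide = pixels_per_slide,
                 tissue_fraction = tissue_fraction,
                 roi_given_tissue = roi_given_tissue,
                 filesize_model = filesize_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Solve the log-normal noise sd of the compression curve so that the raw-scale
# Pearson correlation between pixels and bytes hits the target. With
# U = log(pixels) ~ N(., s^2) and log(bytes) = log a + b*U + N(0, sigma^2),
# corr(e^U, e^V) = (e^{b s^2} - 1) / sqrt((e^{s^2}-1)(e^{b^2 s^2 + sigma^2}-1)),
# which inverts in closed form for sigma.
filesize_noise_sd <- function(target_r, exponent_b, sdlog_pixels) {
  s2 <- sdlog_pixels^2
  if (s2 == 0) {
    stop("configuration error in field `pixels_per_slide`: zero spread, correlation target unreachable",
         call. = FALSE)
  }
  v <- ((exp(exponent_b * s2) - 1) / target_r)^2 / (exp(s2) - 1)
  sig2 <- log1p(v) - exponent_b^2 * s2
  if (!is.finite(sig2) || sig2 < 0) {
    stop("configuration error in field `filesize_model$target_correlation`: target too high for the configured pixel spread",
         call. = FALSE)
  }
  sqrt(sig2)
}

#' Generate a synthetic slide cohort
#'
#' Draws cases and slides from the distributions in `config`, deterministically
#' for a fixed seed. The returned slide table satisfies all invariants:
#' `roi_fraction <= tissue_fraction <= 1`, positive pixel and byte counts, and
#' each case's `n_slides` equal to its number of slide rows.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `cases` (data frame:
#'   `case_id`, `organ`, `specimen_type`, `n_slides`) and `slides` (data
#'   frame: `slide_id`, `case_id`, `organ`, `specimen_type`, `n_pixels`,
#'   `file_size_bytes`, `tissue_fraction`, `roi_fraction`), plus the seed
#'   recorded as attribute `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' nrow(coh$cases)  # 13 cases: 5 prostate + 8 breast
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  organs <- names(config$n_cases)

  set.seed(substream_seed(config$seed, "cases"))
  cases <- do.call(rbind, lapply(organs, function(org) {
    n <- config$n_cases[[org]]
    data.frame(
      case_id = sprintf("%s_case_%02d", org, seq_len(n)),
      organ = org,
      specimen_type = paste0(org, " specimen"),
      n_slides = pmax(1L, as.integer(round(sample_dist(config$slides_per_case, n)))),
      stringsAsFactors = FALSE
    )
  }))

  set.seed(substream_seed(config$seed, "slides"))
  idx <- rep(seq_len(nrow(cases)), cases$n_slides)
  n_slides <- length(idx)
  slide_no <- stats::ave(idx, idx, FUN = seq_along)
  n_pixels <- pmax(1, round(sample_dist(config$pixels_per_slide, n_slides)))
  tissue <- pmin(1, pmax(0, sample_dist(config$tissue_fraction, n_slides)))
  roi <- tissue * pmin(1, pmax(0, sample_dist(config$roi_given_tissue, n_slides)))

  fm <- config$filesize_model
  sd_noise <- filesize_noise_sd(fm$target_correlation, fm$exponent_b,
                                config$pixels_per_slide$params$sdlog)
  bytes <- pmax(1, round(fm$coef_a * n_pixels^fm$exponent_b *
                           exp(stats::rnorm(n_slides, 0, sd_noise))))

  slides <- data.frame(
    slide_id = sprintf("%s_s%03d", cases$case_id[idx], slide_no),
    case_id = cases$case_id[idx],
    organ = cases$organ[idx],
    specimen_type = cases$specimen_type[idx],
    n_pixels = n_pixels,
    file_size_bytes = bytes,
    tissue_fraction = tissue,
    roi_fraction = roi,
    stringsAsFactors = FALSE
  )
  structure(list(cases = cases, slides = slides),
            class = "cohort", seed = config$seed)
}

#' Tile counts for slides under a tiling specification
#'
#' Number of square, non-overlapping tiles a deep-learning model would
#' process for each slide. In `"wsi"` mode every tile of the scanned area
#' counts: `ceiling(n_pixels / tile_edge_px^2)`. In `"tissue"` and `"roi"`
#' modes only the corresponding area fraction is kept, with a ceiling so a
#' partially covered tile still costs a full inference. Because
#' `roi_fraction <= tissue_fraction <= 1`, counts always satisfy
#' `roi <= tissue <= wsi`.
#'
#' @param slides Data frame with columns `n_pixels`, `tissue_fraction`,
#'   `roi_fraction` (a full slide table or any subset of rows).
#' @param tiling A [tiling_spec()].
#' @return Integer-valued numeric vector, one count per row.
#' @export
tiles_per_slide <- function(slides, tiling = tiling_spec()) {
  assert_columns(slides, "n_pixels", "slide table")
  if (any(slides$n_pixels < 1)) stop("n_pixels must be >= 1", call. = FALSE)
  wsi <- ceiling(slides$n_pixels / tiling$tile_edge_px^2)
  switch(tiling$mode,
    wsi = wsi,
    tissue = {
      assert_columns(slides, "tissue_fraction", "slide table")
      ceiling(wsi * slides$tissue_fraction)
    },
    roi = {
      assert_columns(slides, "roi_fraction", "slide table")
      ceiling(wsi * slides$roi_fraction)
    }
  )
}

#' Tiling specification
#'
#' @param tile_edge_px Tile edge in pixels (default 512, a common patch size
#'   in computational pathology).
#' @param mode Data-input mode: `"wsi"` (all tiles), `"tissue"` (tiles
#'   containing tissue) or `"roi"` (tiles inside the region of interest).
#' @return An object of class `tiling_spec`.
#' @export
tiling_spec <- function(tile_edge_px = 512L, mode = c("wsi", "tissue", "roi")) {
  mode <- match.arg(mode)
  assert_number(tile_edge_px, "tile_edge_px", lower = 1)
  structure(list(tile_edge_px = as.integer(tile_edge_px), mode = mode),
            class = "tiling_spec")
}

#' Aggregate a cohort's tile workload
#'
#' Sums per-slide tile counts into per-case, per-organ and total workloads.
#' The grouping is an exact partition: every slide contributes to exactly one
#' case and one organ, and the totals equal the sum of the per-slide counts.
#'
#' @param slides Slide table (or a `cohort` object, whose `$slides` is used).
#' @param tiling A [tiling_spec()].
#' @return A list of class `cohort_workload` with `per_slide`, `per_case`,
#'   `per_organ` data frames, `total` tile count, and the tiling used.
#' @export
cohort_workload <- function(slides, tiling = tiling_spec()) {
  if (inherits(slides, "cohort")) slides <- slides$slides
  if (is.null(slides) || nrow(slides) == 0L) {
    stop("empty cohort: no slides to tally", call. = FALSE)
  }
  tiles <- tiles_per_slide(slides, tiling)
  per_slide <- data.frame(slide_id = slides$slide_id, case_id = slides$case_id,
                          organ = slides$organ, tiles = tiles,
                          stringsAsFactors = FALSE)
  per_case <- stats::aggregate(tiles ~ case_id + organ, data = per_slide, FUN = sum)
  per_organ <- stats::aggregate(tiles ~ organ, data = per_slide, FUN = sum)
  structure(list(per_slide = per_slide,
                 per_case = per_case[order(per_case$case_id), , drop = FALSE],
                 per_organ = per_organ,
                 total = sum(tiles),
                 tiling = tiling),
            class = "cohort_workload")
}

#' Validate a cohort against its structural invariants
#'
#' Report-only check: never throws. Flags ROI fractions exceeding tissue
#' fractions, fractions outside \[0,1\], non-positive pixel or byte counts,
#' orphan slides (a `case_id` absent from the case table) and case rows whose
#' `n_slides` disagrees with the slide table.
#'
#' @param slides Slide table.
#' @param cases Optional case table; case-level checks are skipped when `NULL`.
#' @return Data frame with columns `id`, `field`, `problem`; zero rows iff
#'   the cohort is valid.
#' @export
validate_cohort <- function(slides, cases = NULL) {
  if (inherits(slides, "cohort")) {
    cases <- cases %||% slides$cases
    slides <- slides$slides
  }
  bad <- list()
  flag <- function(id, field, problem) {
    data.frame(id = id, field = field, problem = problem, stringsAsFactors = FALSE)
  }
  i <- which(slides$roi_fraction > slides$tissue_fraction + 1e-12)
  if (length(i)) bad[[length(bad) + 1L]] <-
    flag(slides$slide_id[i], "roi_fraction", "roi_fraction exceeds tissue_fraction")
  i <- which(slides$tissue_fraction < 0 | slides$tissue_fraction > 1)
  if (length(i)) bad[[length(bad) + 1L]] <-
    flag(slides$slide_id[i], "tissue_fraction", "tissue_fraction outside [0, 1]")
  i <- which(slides$roi_fraction < 0)
  if (length(i)) bad[[length(bad) + 1L]] <-
    flag(slides$slide_id[i], "roi_fraction", "roi_fraction negative")
  i <- which(slides$n_pixels < 1)
  if (length(i)) bad[[length(bad) + 1L]] <-
    flag(slides$slide_id[i], "n_pixels", "n_pixels not positive")
  i <- which(slides$file_size_bytes < 1)
  if (length(i)) bad[[length(bad) + 1L]] <-
    flag(slides$slide_id[i], "file_size_bytes", "file_size_bytes not positive")
  if (!is.null(cases)) {
    i <- which(!(slides$case_id %in% cases$case_id))
    if (length(i)) bad[[length(bad) + 1L]] <-
      flag(slides$slide_id[i], "case_id", "orphan slide: case_id not in case table")
    counts <- table(slides$case_id)
    for (j in seq_len(nrow(cases))) {
      seen <- if (cases$case_id[j] %in% names(counts)) counts[[cases$case_id[j]]] else 0L
      if (seen != cases$n_slides[j]) {
        bad[[length(bad) + 1L]] <- flag(cases$case_id[j], "n_slides",
          sprintf("n_slides is %d but %d slide rows reference this case",
                  cases$n_slides[j], seen))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(id = character(), field = character(), problem = character(),
               stringsAsFactors = FALSE)
}

#' Read / write a cohort slide table as CSV
#'
#' One row per slide: `slide_id`, `case_id`, `organ`, `specimen_type`,
#' `n_pixels`, `file_size_bytes`, `tissue_fraction`, `roi_fraction`; UTF-8
#' with a header row, fractions as decimals in \[0,1\].
#'
#' @param path CSV file path.
#' @return `read_cohort_csv` returns a `cohort` (cases reconstructed by
#'   aggregation); `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  slides <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(slides, c("slide_id", "case_id", "organ", "n_pixels",
                           "file_size_bytes", "tissue_fraction", "roi_fraction"),
                 "cohort CSV")
  if (is.null(slides$specimen_type)) slides$specimen_type <- NA_character_
  cases <- stats::aggregate(slide_id ~ case_id + organ + specimen_type,
                            data = slides, FUN = length)
  names(cases)[names(cases) == "slide_id"] <- "n_slides"
  cases <- cases[order(cases$case_id), c("case_id", "organ", "specimen_type", "n_slides")]
  rownames(cases) <- NULL
  structure(list(cases = cases, slides = slides), class = "cohort")
}

#' @rdname read_cohort_csv
#' @param cohort A `cohort` object or a slide table.
#' @export
write_cohort_csv <- function(cohort, path) {
  slides <- if (inherits(cohort, "cohort")) cohort$slides else cohort
  utils::write.csv(slides, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
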