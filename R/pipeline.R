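#' Pipeline configuration
#'
#' Collects every tunable of the mapping + landmarking + statistics
#' pipeline, with the reference defaults: 7.5-mm sampling sphere on a
#' 3.5-mm background grid, 1-mm scalar mesh, 80th-percentile internal
#' regions, 5 + 4x7 + 208 landmark template, 9999 permutations.
#'
#' @param sphere_diameter_mm BV/TV sampling sphere diameter.
#' @param grid_spacing_mm background grid spacing.
#' @param mesh_size_mm scalar mesh element size.
#' @param percentile internal-region percentile (75, 80 or 85 typical).
#' @param rim_z_mm height of the head-neck boundary plane in the
#'   canonical frame; the scalar mesh covers the head above it.
#' @param grid_min_coverage minimum in-mask sphere coverage for a
#'   background-grid node to enter the interpolation.
#' @param n_curve,n_surf,n_divider landmark template counts.
#' @param region_min_elements speck floor (elements) for the internal
#'   region count; components below it are noise, far below the blob
#'   scale (see [percentile_regions()]).
#' @param smoothing_iters surface smoothing iterations.
#' @param n_perm permutations for the pairwise permutational MANOVA.
#' @param n_components PCs tested (default 3).
#' @param seed base seed for stochastic stages.
#' @param slide_rounds Procrustes-sliding rounds.
#' @param relax_iters bending-energy relaxation iteration cap.
#' @param relax_tol relative energy-change tolerance for the relaxation
#'   (the pipeline uses a looser tolerance than the operation default:
#'   semilandmark positions stop changing at BV/TV-relevant scales well
#'   before the energy plateaus to machine precision).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sphere_diameter_mm = 7.5, grid_spacing_mm = 3.5,
                            mesh_size_mm = 1.0, percentile = 80,
                            region_min_elements = 8L, rim_z_mm = 0,
                            grid_min_coverage = 0.25,
                            n_curve = 7L, n_surf = 208L, n_divider = 32L,
                            smoothing_iters = 30L, n_perm = 9999L,
                            n_components = 3L, seed = 1L,
                            slide_rounds = 2L, relax_iters = 10L,
                            relax_tol = 1e-3) {
  cfg <- list(sphere_diameter_mm = sphere_diameter_mm,
              grid_spacing_mm = grid_spacing_mm,
              mesh_size_mm = mesh_size_mm, percentile = percentile,
              region_min_elements = region_min_elements,
              rim_z_mm = rim_z_mm, grid_min_coverage = grid_min_coverage,
              n_curve = n_curve, n_surf = n_surf, n_divider = n_divider,
              smoothing_iters = smoothing_iters, n_perm = n_perm,
              n_components = n_components, seed = seed,
              slide_rounds = slide_rounds, relax_iters = relax_iters,
              relax_tol = relax_tol)
  stopifnot(sphere_diameter_mm > 0, grid_spacing_mm > 0, mesh_size_mm > 0,
            percentile > 0, percentile < 100)
  structure(cfg, class = "pipeline_config")
}

#' Map one specimen: background grid, BV/TV field, internal regions
#'
#' @param volume a binary `bone_volume` with an outer mask.
#' @param config a `pipeline_config`.
#' @return list with `grid` (sampled), `mesh` (`scalar_mesh`), `regions`
#'   (`region_labels`).
#' @export
map_specimen <- function(volume, config = pipeline_config()) {
  volume <- reorient_canonical(volume)
  grid <- seed_background_grid(volume, config$grid_spacing_mm)
  grid <- sample_grid_bvtv(volume, grid, config$sphere_diameter_mm,
                           config$grid_min_coverage)
  mesh <- build_scalar_mesh(volume, grid, config$mesh_size_mm,
                            zmin_mm = config$rim_z_mm)
  regions <- percentile_regions(mesh, config$percentile,
                                config$region_min_elements)
  list(grid = grid, mesh = mesh, regions = regions)
}

#' Landmark one specimen and extract landmark BV/TV
#'
#' @param volume binary `bone_volume`.
#' @param mesh the specimen's `scalar_mesh`.
#' @param template a `landmark_template`.
#' @param config a `pipeline_config`.
#' @param id specimen identifier.
#' @return a `landmark_set` with per-landmark BV/TV in `$bvtv`.
#' @export
landmark_specimen <- function(volume, mesh, template,
                              config = pipeline_config(), id = "specimen") {
  volume <- reorient_canonical(volume)
  surf <- extract_subchondral_surface(
    bone_volume(mask_array(volume), volume$voxel_mm, volume$origin_mm,
                "binary"),
    smoothing_iters = config$smoothing_iters)
  # relaxation stopping at the iteration budget is expected here; it is
  # recorded (and surfaced in the report) rather than emitted per call
  warns <- character(0)
  set <- withCallingHandlers(
    place_landmarks(surf, template, id = id,
                    max_iter = config$relax_iters,
                    tol = config$relax_tol),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  set$bvtv <- as.numeric(bvtv_at_landmarks(set, mesh))
  attr(set, "warnings") <- warns
  set
}

#' Run the full comparison on an in-memory cohort
#'
#' Maps every specimen, places and slides landmarks across the cohort,
#' assembles the RBV/TV matrix, and runs PCA plus Bonferroni-corrected
#' pairwise permutational MANOVA on the leading PCs.
#'
#' @param specimens list of specimens: each a list with `volume` (binary
#'   `bone_volume`), `group`, `id` (e.g. from [make_cohort()]).
#' @param config a `pipeline_config`.
#' @param template optional prebuilt `landmark_template`.
#' @return an `epiphysis_comparison`: per-specimen maps and landmark
#'   sets, `rbvtv` matrix, `pca`, `permanova`, `component_counts`.
#' @export
analyze_cohort <- function(specimens, config = pipeline_config(),
                           template = NULL) {
  if (is.null(template))
    template <- build_template(config$n_curve, config$n_surf,
                               config$n_divider)
  maps <- vector("list", length(specimens))
  sets <- vector("list", length(specimens))
  for (i in seq_along(specimens)) {
    sp <- specimens[[i]]
    maps[[i]] <- map_specimen(sp$volume, config)
    sets[[i]] <- landmark_specimen(sp$volume, maps[[i]]$mesh, template,
                                   config, id = sp$id)
  }
  if (config$slide_rounds > 0L && length(sets) >= 2L) {
    sets <- slide_to_mean(sets, max_rounds = config$slide_rounds)
    for (i in seq_along(sets))
      sets[[i]]$bvtv <- as.numeric(bvtv_at_landmarks(sets[[i]],
                                                     maps[[i]]$mesh))
  }
  groups <- vapply(specimens, `[[`, character(1), "group")
  ids <- vapply(specimens, `[[`, character(1), "id")
  rb <- rbvtv_matrix(lapply(sets, `[[`, "bvtv"), ids = ids, groups = groups)
  pca <- pca_rbvtv(rb)
  k <- min(choose_components(pca), config$n_components,
           length(pca$variance_fraction))
  pm <- if (length(unique(groups)) >= 2)
    pairwise_permanova(pca$scores, groups, n_components = k,
                       n_perm = config$n_perm, seed = config$seed)
  counts <- vapply(maps, function(m) m$regions$n_components, integer(1))
  structure(list(maps = maps, landmarks = sets, rbvtv = rb, pca = pca,
                 permanova = pm, component_counts = counts,
                 groups = groups, ids = ids, config = config),
            class = "epiphysis_comparison")
}

#' @export
print.epiphysis_comparison <- function(x, ...) {
  cat(sprintf("<epiphysis_comparison> %d specimens in %d group(s)\n",
              length(x$ids), length(unique(x$groups))))
  cat(sprintf("  PC1-3 variance: %s\n",
              paste(sprintf("%.1f%%", 100 * head(x$pca$variance_fraction, 3)),
                    collapse = " / ")))
  ct <- table(x$groups, x$component_counts)
  cat("  internal components (rows = group):\n")
  print(ct)
  if (!is.null(x$permanova)) {
    cat("  pairwise permutational MANOVA:\n")
    print(as.data.frame(x$permanova))
  }
  invisible(x)
}

#' Run the file-based pipeline over a cohort manifest
#'
#' Stages per specimen: read volume, map BV/TV, landmark; then cohort
#' statistics.  Per-specimen stage outputs are written under `out_dir`
#' and skipped on reruns when the input file's checksum and the config
#' echo are unchanged.  A specimen whose processing fails is flagged and
#' reported; the rest of the cohort completes.
#'
#' @param manifest data frame with columns `id`, `path` (volume file or
#'   TIFF-stack directory), `group`.
#' @param out_dir output directory.
#' @param config a `pipeline_config`.
#' @return a `run_record`: per-specimen status, timings and hashes, the
#'   cohort results (as from [analyze_cohort()]) for the successful
#'   specimens, and the paths of all written outputs.
#' @export
run_pipeline <- function(manifest, out_dir, config = pipeline_config()) {
  stopifnot(all(c("id", "path", "group") %in% names(manifest)))
  if (nrow(manifest) == 0L) stop("empty manifest")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- hash_object(unclass(config))
  template <- build_template(config$n_curve, config$n_surf, config$n_divider)
  status <- data.frame(id = manifest$id, stage = "pending",
                       ok = FALSE, skipped = FALSE, seconds = NA_real_,
                       input_hash = NA_character_, message = "",
                       stringsAsFactors = FALSE)
  done <- list()  # id -> list(map, set, group, hash)
  for (i in seq_len(nrow(manifest))) {
    t0 <- proc.time()[3]
    row <- manifest[i, ]
    warns <- character(0)
    res <- tryCatch(withCallingHandlers({
      ih <- hash_path(row$path)
      status$input_hash[i] <- ih
      cache_rds <- file.path(out_dir, paste0(row$id, "_specimen.rds"))
      cache_rec <- file.path(out_dir, paste0(row$id, "_specimen.json"))
      hit <- file.exists(cache_rds) && file.exists(cache_rec) && {
        rec <- jsonlite::read_json(cache_rec, simplifyVector = TRUE)
        identical(rec$input_hash, ih) && identical(rec$config_hash, cfg_hash)
      }
      if (hit) {
        obj <- readRDS(cache_rds)
        obj$skipped <- TRUE
        obj
      } else {
        vol <- read_volume(row$path)
        mp <- map_specimen(vol, config)
        st <- landmark_specimen(vol, mp$mesh, template, config, id = row$id)
        obj <- list(map = mp, set = st, skipped = FALSE)
        saveRDS(obj, cache_rds)
        jsonlite::write_json(list(input_hash = ih, config_hash = cfg_hash),
                             cache_rec, auto_unbox = TRUE)
        write_specimen_outputs(out_dir, row$id, mp, st)
        obj
      }
    }, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    status$seconds[i] <- proc.time()[3] - t0
    if (length(warns))
      status$message[i] <- paste("warning:", paste(warns, collapse = "; "))
    if (inherits(res, "error")) {
      status$stage[i] <- "map"
      status$message[i] <- paste(conditionMessage(res), status$message[i])
      next
    }
    status$stage[i] <- "map"; status$ok[i] <- TRUE
    status$skipped[i] <- res$skipped
    done[[row$id]] <- c(res, list(group = row$group,
                                  hash = status$input_hash[i]))
  }
  results <- NULL
  cohort_skipped <- FALSE
  if (length(done) >= 3L &&
      length(unique(vapply(done, `[[`, character(1), "group"))) >= 2L) {
    cohort_key <- paste(cfg_hash,
                        paste(vapply(done, `[[`, character(1), "hash"),
                              collapse = ""), sep = ":")
    co_rds <- file.path(out_dir, "cohort.rds")
    co_rec <- file.path(out_dir, "cohort.json")
    hit <- file.exists(co_rds) && file.exists(co_rec) &&
      identical(jsonlite::read_json(co_rec,
                                    simplifyVector = TRUE)$key, cohort_key)
    if (hit) {
      results <- readRDS(co_rds)
      cohort_skipped <- TRUE
    } else {
      results <- cohort_statistics(done, config, template)
      saveRDS(results, co_rds)
      jsonlite::write_json(list(key = cohort_key), co_rec,
                           auto_unbox = TRUE)
      write_cohort_outputs(out_dir, results)
    }
  }
  structure(list(status = status, results = results, out_dir = out_dir,
                 config = config, config_hash = cfg_hash,
                 cohort_skipped = cohort_skipped),
            class = "run_record")
}

# cohort-level sliding + statistics over per-specimen stage outputs
cohort_statistics <- function(done, config, template) {
  sets <- lapply(done, `[[`, "set")
  maps <- lapply(done, `[[`, "map")
  if (config$slide_rounds > 0L && length(sets) >= 2L) {
    sets <- slide_to_mean(sets, max_rounds = config$slide_rounds)
    for (i in seq_along(sets))
      sets[[i]]$bvtv <- as.numeric(bvtv_at_landmarks(sets[[i]],
                                                     maps[[i]]$mesh))
  }
  groups <- vapply(done, `[[`, character(1), "group")
  ids <- names(done)
  rb <- rbvtv_matrix(lapply(sets, `[[`, "bvtv"), ids = ids, groups = groups)
  pca <- pca_rbvtv(rb)
  k <- min(choose_components(pca), config$n_components,
           length(pca$variance_fraction))
  pm <- pairwise_permanova(pca$scores, groups, n_components = k,
                           n_perm = config$n_perm, seed = config$seed)
  counts <- vapply(maps, function(m) m$regions$n_components, integer(1))
  structure(list(maps = maps, landmarks = sets, rbvtv = rb, pca = pca,
                 permanova = pm, component_counts = counts,
                 groups = unname(groups), ids = ids, config = config),
            class = "epiphysis_comparison")
}

hash_path <- function(path) {
  if (dir.exists(path)) {
    fs <- sort(list.files(path, full.names = TRUE))
    paste(unname(tools::md5sum(fs)), collapse = "")
  } else unname(tools::md5sum(path))
}

hash_object <- function(x) {
  f <- tempfile(); on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12), f)
  unname(tools::md5sum(f))
}

write_specimen_outputs <- function(out_dir, id, mp, st) {
  g <- mp$grid
  utils::write.csv(data.frame(x = g$nodes[, 1], y = g$nodes[, 2],
                              z = g$nodes[, 3], bvtv = g$bvtv),
                   file.path(out_dir, paste0(id, "_grid.csv")),
                   row.names = FALSE)
  utils::write.csv(data.frame(x = mp$mesh$centers[, 1],
                              y = mp$mesh$centers[, 2],
                              z = mp$mesh$centers[, 3],
                              bvtv = mp$mesh$values,
                              component = mp$regions$component),
                   file.path(out_dir, paste0(id, "_mesh.csv")),
                   row.names = FALSE)
  utils::write.csv(data.frame(id = id, role = st$role,
                              quarter = st$quarter,
                              x = st$points[, 1], y = st$points[, 2],
                              z = st$points[, 3], bvtv = st$bvtv),
                   file.path(out_dir, paste0(id, "_landmarks.csv")),
                   row.names = FALSE)
}

write_cohort_outputs <- function(out_dir, results) {
  rb <- results$rbvtv
  m <- as.data.frame(rb$x)
  names(m) <- sprintf("lm%03d", seq_len(ncol(m)))
  utils::write.csv(cbind(data.frame(id = rb$ids, group = rb$groups), m),
                   file.path(out_dir, "rbvtv_matrix.csv"), row.names = FALSE)
  sc <- as.data.frame(results$pca$scores)
  names(sc) <- sprintf("PC%d", seq_len(ncol(sc)))
  utils::write.csv(cbind(data.frame(id = results$ids,
                                    group = results$groups), sc),
                   file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    component = seq_along(results$pca$variance_fraction),
    variance_fraction = results$pca$variance_fraction),
    file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
  if (!is.null(results$permanova))
    utils::write.csv(as.data.frame(results$permanova),
                     file.path(out_dir, "permanova.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = results$ids, group = results$groups,
                              n_components = results$component_counts),
                   file.path(out_dir, "internal_components.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Render a Markdown report for a pipeline run
#'
#' Self-contained Markdown: provenance block (config echo and hashes),
#' per-specimen status, internal component counts, PCA variance table,
#' and the permutational MANOVA table.  If ggplot2 is available, a PC1
#' vs PC2 scatter is saved next to the report and embedded.
#'
#' @param run a `run_record` from [run_pipeline()].
#' @param path output file (default `report.md` in the run directory).
#' @return the report path, invisibly.
#' @export
make_report <- function(run, path = file.path(run$out_dir, "report.md")) {
  if (is.null(run$results))
    stop("statistics stage is missing: nothing to report")
  res <- run$results
  lines <- c("# Trabecular BV/TV distribution report", "",
             "## Provenance", "",
             paste0("- config hash: `", run$config_hash, "`"),
             paste0("- ", names(unclass(run$config)), " = ",
                    vapply(unclass(run$config), function(v)
                      paste(format(v), collapse = ","), character(1))),
             "", "## Specimens", "",
             "| id | stage | ok | skipped | warnings | input hash |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %s | %s |", run$status$id,
                     run$status$stage, run$status$ok, run$status$skipped,
                     vapply(run$status$id, function(id) {
                       i <- match(id, res$ids)
                       if (is.na(i)) "" else
                         paste(attr(res$landmarks[[i]], "warnings"),
                               collapse = "; ")
                     }, character(1)),
                     substr(run$status$input_hash, 1, 8)),
             "", "## Internal high-BV/TV components (above percentile)", "",
             "| id | group | components |", "|---|---|---|",
             sprintf("| %s | %s | %d |", res$ids, res$groups,
                     res$component_counts),
             "", "## PCA variance fractions", "",
             paste0("PC", seq_along(res$pca$variance_fraction), ": ",
                    sprintf("%.1f%%", 100 * res$pca$variance_fraction),
                    collapse = "; "))
  if (!is.null(res$permanova)) {
    pm <- as.data.frame(res$permanova)
    lines <- c(lines, "", "## Pairwise permutational MANOVA", "",
               "| A | B | F | p | p (Bonferroni) |", "|---|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.4g | %.4g |", pm$group_a,
                       pm$group_b, pm$F, pm$p, pm$p_adjusted))
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    df <- data.frame(PC1 = res$pca$scores[, 1],
                     PC2 = if (ncol(res$pca$scores) > 1)
                       res$pca$scores[, 2] else 0,
                     group = res$groups)
    gp <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                           colour = .data$group)) +
      ggplot2::geom_point(size = 2) + ggplot2::theme_minimal()
    img <- file.path(dirname(path), "pca_scatter.png")
    ggplot2::ggsave(img, gp, width = 5, height = 4, dpi = 120)
    lines <- c(lines, "", "## RBV/TV PCA", "",
               sprintf("![PCA scatter](%s)", basename(img)))
  }
  writeLines(lines, path)
  invisible(path)
}
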