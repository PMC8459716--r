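#' Analysis configuration
#'
#' @param rows,cols Atlas grid dimensions (default 132 x 40).
#' @param threshold Segment inclusion threshold as a fraction (default 0.05).
#' @param min_per_organ Minimum patients per organ group (default 4).
#' @param sacral_front Forwarded to [build_schematic_atlas()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(rows = 132L, cols = 40L, threshold = 0.05,
                            min_per_organ = 4L, sacral_front = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1, min_per_organ >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 threshold = threshold,
                 min_per_organ = as.integer(min_per_organ),
                 sacral_front = isTRUE(sacral_front)),
            class = "analysis_config")
}

#' Write a mean body map as NIfTI (fractions) and PNG preview
#'
#' @param mmap A `mean_body_map`.
#' @param nii_path,png_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, `mmap`.
#' @export
write_mean_map <- function(mmap, nii_path = NULL, png_path = NULL) {
  stopifnot(inherits(mmap, "mean_body_map"))
  if (!is.null(nii_path)) {
    vol <- array(0, dim = c(dim(mmap$front), 2L))
    vol[, , 1L] <- mmap$front
    vol[, , 2L] <- mmap$back
    RNifti::writeNifti(RNifti::asNifti(vol), nii_path, datatype = "float")
  }
  if (!is.null(png_path)) {
    canvas <- cbind(mmap$front, 0, mmap$back)
    png::writePNG(1 - canvas / max(max(canvas), 1e-12), png_path)
  }
  invisible(mmap)
}

#' Demographic summary of a cohort
#'
#' @param x A non-empty `cohort`; missing ages/sexes are tolerated.
#' @return data.frame with columns `field`, `value`: patient count, mean and
#'   SD of age (`NA` when no ages are recorded; SD 0 for a single age), sex
#'   counts and per-organ counts.
#' @export
demographics_summary <- function(x) {
  validate_cohort(x)
  if (!length(x$patients)) stop("demographics_summary: empty cohort",
                                call. = FALSE)
  ages <- vapply(x$patients, `[[`, numeric(1), "age")
  sexes <- vapply(x$patients, `[[`, character(1), "sex")
  organs <- cohort_organs(x)
  ages <- ages[!is.na(ages)]
  age_mean <- if (length(ages)) mean(ages) else NA_real_
  age_sd <- if (length(ages) > 1L) stats::sd(ages) else
    if (length(ages) == 1L) 0 else NA_real_
  rows <- data.frame(
    field = c("n", "age_mean", "age_sd", "n_female", "n_male"),
    value = c(length(x$patients), age_mean, age_sd,
              sum(sexes == "female", na.rm = TRUE),
              sum(sexes == "male", na.rm = TRUE)),
    stringsAsFactors = FALSE)
  tab <- table(organs)
  rbind(rows, data.frame(field = paste0("organ_", names(tab)),
                         value = as.numeric(tab), stringsAsFactors = FALSE))
}

#' Run the full body-map analysis and write the result bundle
#'
#' Applies the single-organ selection, builds the atlas, and writes to
#' `out_dir`: the cohort-wide frequency table and demographics, the
#' per-organ lateralization summary, per-organ per-sign segment coverage
#' tables, per-organ mean maps of all segmental signs and of spontaneous
#' pain (NIfTI fraction volumes plus PNG previews), the mean number of signs
#' per half segment, and a machine-readable run manifest. The run is fully
#' deterministic given the cohort and configuration.
#'
#' @param x A `cohort` or a path to a cohort JSON file.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed tables and mean maps.
#' @export
run_analysis <- function(x, config = analysis_config(),
                         out_dir = "segmap-results") {
  if (is.character(x)) x <- read_cohort(x)
  validate_cohort(x)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))

  selected <- select_single_organ(x, config$min_per_organ)
  if (!length(selected$patients))
    stop("run_analysis: no patients left after single-organ selection",
         call. = FALSE)
  atlas <- build_schematic_atlas(config$rows, config$cols,
                                 config$sacral_front)

  freq <- frequency_table(selected)
  utils::write.csv(freq, path("frequency.csv"), row.names = FALSE)
  demo <- demographics_summary(selected)
  utils::write.csv(demo, path("demographics.csv"), row.names = FALSE)

  organs <- intersect(analyzable_organs(), unique(cohort_organs(selected)))
  latrows <- list(); covrows <- list(); msrows <- list()
  maps <- list()
  for (org in organs) {
    latrows[[org]] <- lateralization_summary(selected, org)

    mm_signs <- mean_map(selected, org, "all_signs", atlas)
    mm_pain <- mean_map(selected, org, "pain", atlas)
    write_mean_map(mm_signs, path("meanmap_", org, "_signs.nii.gz"),
                   path("meanmap_", org, "_signs.png"))
    write_mean_map(mm_pain, path("meanmap_", org, "_pain.nii.gz"),
                   path("meanmap_", org, "_pain.png"))
    maps[[org]] <- list(all_signs = mm_signs, pain = mm_pain)

    org_patients <- Filter(function(p) p$organ == org, selected$patients)
    for (s in distributed_signs()) {
      drawn <- any(vapply(org_patients, function(p)
        any(vapply(p$drawings, function(d) d$sign == s, logical(1))),
        logical(1)))
      if (!drawn) next
      umap <- superimpose_binarize(lapply(org_patients, patient_sign_map,
                                          atlas = atlas, signs = s))
      cov <- segment_coverage(umap, atlas, config$threshold)
      covrows[[paste(org, s)]] <- cbind(organ = org, sign = s, cov)
    }

    ms <- mean_signs_per_half_segment(selected, org, atlas, config$threshold)
    msrows[[org]] <- cbind(organ = org, ms)
  }
  lat <- do.call(rbind, latrows); rownames(lat) <- NULL
  cov <- do.call(rbind, covrows); rownames(cov) <- NULL
  ms <- do.call(rbind, msrows); rownames(ms) <- NULL
  utils::write.csv(lat, path("lateralization.csv"), row.names = FALSE)
  utils::write.csv(cov, path("coverage.csv"), row.names = FALSE)
  utils::write.csv(ms, path("mean_signs_per_half_segment.csv"),
                   row.names = FALSE)

  sel_drop <- attr(selected, "dropped")
  manifest <- list(
    package = "segmapr",
    version = as.character(utils::packageVersion("segmapr")),
    config = unclass(config),
    cohort_meta = x$meta,
    selection = list(n_input = attr(selected, "n_input"),
                     n_retained = attr(selected, "n_retained"),
                     dropped = as.list(sel_drop)),
    organs_analyzed = organs)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(selected = selected, atlas = atlas, frequency = freq,
                 demographics = demo, lateralization = lat, coverage = cov,
                 mean_signs = ms, mean_maps = maps))
}
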