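#' Construct a drawing record
#'
#' One distributed finding as drawn on the body template: a sign token, the
#' template view it was drawn on, and one or more closed polygons in
#' normalized `[0,1] x [0,1]` coordinates (x across, y down, origin top-left).
#'
#' @param sign One of [distributed_signs()].
#' @param view `"front"` or `"back"`.
#' @param polygons A single `n x 2` matrix or a list of such matrices, each
#'   with at least 3 vertices. A matrix may carry a logical attribute
#'   `closed = FALSE` to mark an open stroke.
#' @return A `drawing_record`.
#' @export
drawing_record <- function(sign, view, polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  d <- structure(list(sign = sign, view = view, polygons = polygons),
                 class = "drawing_record")
  .check_drawing(d, id = "<unattached>")
  d
}

.check_drawing <- function(d, id) {
  if (!d$sign %in% distributed_signs())
    stop("patient '", id, "': unknown sign token '", d$sign, "'",
         call. = FALSE)
  if (!d$view %in% body_views())
    stop("patient '", id, "': invalid view '", d$view, "'", call. = FALSE)
  for (poly in d$polygons) {
    if (!is.matrix(poly) || ncol(poly) != 2L)
      stop("patient '", id, "': polygon must be an n x 2 matrix",
           call. = FALSE)
    if (nrow(poly) < 3L)
      stop("patient '", id, "': polygon for sign '", d$sign,
           "' has fewer than 3 vertices", call. = FALSE)
    if (any(!is.finite(poly)) || any(poly < 0) || any(poly > 1))
      stop("patient '", id, "': polygon coordinates for sign '", d$sign,
           "' outside [0,1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a patient record
#'
#' @param id Unique patient identifier.
#' @param organ Final single-organ diagnosis group, one of [organ_groups()].
#' @param drawings List of [drawing_record()]s (distributed findings,
#'   including spontaneous pain).
#' @param lateralized List of `list(finding =, side =)` pairs with finding in
#'   [lateralized_findings()] and side `"left"`/`"right"`.
#' @param symptoms Character subset of [segmental_symptoms()].
#' @param age,sex Optional demographics.
#' @param drawings_lost Metadata flag: drawings lost to technical failure;
#'   such patients are excluded by [select_single_organ()].
#' @return A `patient_record`.
#' @export
patient_record <- function(id, organ, drawings = list(), lateralized = list(),
                           symptoms = character(), age = NA_real_,
                           sex = NA_character_, drawings_lost = FALSE) {
  p <- structure(list(id = as.character(id), organ = organ,
                      drawings = drawings, lateralized = lateralized,
                      symptoms = as.character(symptoms), age = age, sex = sex,
                      drawings_lost = isTRUE(drawings_lost)),
                 class = "patient_record")
  .check_patient(p)
  p
}

.check_patient <- function(p) {
  id <- p$id
  if (!nzchar(id)) stop("patient id must be a non-empty string", call. = FALSE)
  if (!p$organ %in% organ_groups())
    stop("patient '", id, "': unknown organ '", p$organ, "'", call. = FALSE)
  for (d in p$drawings) .check_drawing(d, id)
  for (lf in p$lateralized) {
    if (!lf$finding %in% lateralized_findings())
      stop("patient '", id, "': unknown lateralized finding '", lf$finding,
           "'", call. = FALSE)
    if (!lf$side %in% body_sides())
      stop("patient '", id, "': invalid side '", lf$side, "' for finding '",
           lf$finding, "'", call. = FALSE)
  }
  bad <- setdiff(p$symptoms, segmental_symptoms())
  if (length(bad))
    stop("patient '", id, "': unknown symptom '", bad[1], "'", call. = FALSE)
  if (anyDuplicated(p$symptoms))
    stop("patient '", id, "': duplicated symptom tokens", call. = FALSE)
  if (!is.na(p$sex) && !p$sex %in% c("female", "male"))
    stop("patient '", id, "': invalid sex '", p$sex, "'", call. = FALSE)
  invisible(TRUE)
}

#' Construct (and validate) a cohort
#'
#' @param patients List of [patient_record()]s with unique ids.
#' @param meta Provenance list (generator seed, source file, ...).
#' @return A `cohort` object.
#' @export
cohort <- function(patients, meta = list()) {
  x <- structure(list(patients = patients, meta = meta), class = "cohort")
  validate_cohort(x)
  x
}

#' @rdname cohort
#' @param x A `cohort`.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  for (p in x$patients) .check_patient(p)
  ids <- vapply(x$patients, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicated patient id '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  organs <- vapply(x$patients, `[[`, character(1), "organ")
  cat("<cohort> n=", length(x$patients), "\n", sep = "")
  if (length(organs)) print(table(organs))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$patients)

cohort_organs <- function(x) vapply(x$patients, `[[`, character(1), "organ")

# ---- JSON interchange ------------------------------------------------------

.patient_to_json <- function(p) {
  list(
    id = p$id, organ = p$organ,
    age = if (is.na(p$age)) NULL else p$age,
    sex = if (is.na(p$sex)) NULL else p$sex,
    drawings_lost = if (p$drawings_lost) TRUE else NULL,
    drawings = lapply(p$drawings, function(d) list(
      sign = d$sign, view = d$view,
      polygons = lapply(d$polygons, function(poly) {
        pl <- lapply(seq_len(nrow(poly)), function(i) c(poly[i, 1], poly[i, 2]))
        if (identical(attr(poly, "closed"), FALSE))
          list(closed = FALSE, vertices = pl) else list(vertices = pl)
      }))),
    lateralized = lapply(p$lateralized, function(lf)
      list(finding = lf$finding, side = lf$side)),
    symptoms = as.list(p$symptoms))
}

.patient_from_json <- function(j) {
  drawings <- lapply(j$drawings, function(d) {
    polys <- lapply(d$polygons, function(pj) {
      vs <- pj$vertices
      m <- matrix(unlist(vs, use.names = FALSE), ncol = 2L, byrow = TRUE)
      if (identical(pj$closed, FALSE)) attr(m, "closed") <- FALSE
      m
    })
    structure(list(sign = d$sign, view = d$view, polygons = polys),
              class = "drawing_record")
  })
  structure(list(
    id = as.character(j$id %||% ""), organ = j$organ %||% "",
    drawings = drawings,
    lateralized = lapply(j$lateralized, function(lf)
      list(finding = lf$finding, side = lf$side)),
    symptoms = as.character(unlist(j$symptoms, use.names = FALSE)),
    age = as.numeric(j$age %||% NA_real_),
    sex = as.character(j$sex %||% NA_character_),
    drawings_lost = isTRUE(j$drawings_lost)), class = "patient_record")
}

#' Read / write a cohort in the documented JSON dialect
#'
#' The interchange format is plain JSON (schema shipped in
#' `inst/extdata/cohort-schema.json`): a `patients` array of records with
#' `id`, `organ`, `drawings` (polygons as vertex arrays in normalized
#' coordinates), `lateralized` finding/side pairs and `symptoms`, plus a free
#' `meta` object for provenance. Writing then reading reproduces an equal
#' cohort; all records are validated on read and a violation names the
#' offending patient and field.
#'
#' @param path File path.
#' @return `read_cohort` returns a `cohort`; `write_cohort` invisibly
#'   returns `path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$format, "segmap-cohort"))
    stop("not a segmap cohort file (missing format tag): ", path,
         call. = FALSE)
  patients <- lapply(j$patients, .patient_from_json)
  meta <- lapply(j$meta, function(v) if (is.list(v)) v else v)
  cohort(patients, meta = meta %||% list())
}

#' @rdname read_cohort
#' @param x A `cohort`.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  jsonlite::write_json(
    list(format = "segmap-cohort", version = 1L, meta = x$meta,
         patients = lapply(x$patients, .patient_to_json)),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = FALSE)
  invisible(path)
}

#' Apply the single-organ cohort selection
#'
#' Retains patients diagnosed with one of the five analyzable organ groups
#' (heart, lungs, stomach, liver/gallbladder, kidneys/ureters), excluding
#' undiagnosed, multi-organ and unclassified cases as well as patients whose
#' drawings were lost; organ groups with fewer than `min_per_organ` patients
#' are then dropped entirely. Idempotent.
#'
#' @param x A `cohort`.
#' @param min_per_organ Minimum group size for an organ to enter any
#'   organ-specific analysis (default 4).
#' @return The filtered `cohort`; attributes `n_input`, `n_retained` and
#'   `dropped` (named counts per exclusion reason) report the selection.
#' @export
select_single_organ <- function(x, min_per_organ = 4L) {
  validate_cohort(x)
  stopifnot(min_per_organ >= 1L)
  organs <- cohort_organs(x)
  lost <- vapply(x$patients, `[[`, logical(1), "drawings_lost")
  single <- organs %in% analyzable_organs() & !lost
  kept_org <- organs[single]
  sizes <- table(kept_org)
  small <- names(sizes)[sizes < min_per_organ]
  keep <- single & !(organs %in% small)

  dropped <- c(
    not_single_organ = sum(!single & !lost),
    drawings_lost = sum(lost),
    organ_below_minimum = sum(single & organs %in% small))
  out <- structure(list(patients = x$patients[keep],
                        meta = c(x$meta, list(selection = list(
                          min_per_organ = min_per_organ,
                          n_input = length(x$patients))))),
                   class = "cohort")
  if (!length(out$patients))
    warning("single-organ selection produced an empty cohort", call. = FALSE)
  attr(out, "n_input") <- length(x$patients)
  attr(out, "n_retained") <- length(out$patients)
  attr(out, "dropped") <- dropped
  out
}

# ---- mask NIfTI ------------------------------------------------------------

#' Export / import a binary body map as NIfTI
#'
#' Masks are stored as unsigned 8-bit volumes of shape `rows x cols x 2`
#' (slice 1 front, slice 2 back) with an identity affine; reading back gives
#' an identical mask.
#'
#' @param mask A `body_map` (binary).
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `export_mask_nifti` invisibly returns `path`; `read_mask_nifti`
#'   returns a `body_map`.
#' @export
export_mask_nifti <- function(mask, path) {
  if (!is_body_map(mask)) stop("export_mask_nifti: not a body_map")
  vals <- c(mask$front, mask$back)
  if (!all(vals %in% c(0L, 1L)))
    stop("export_mask_nifti: mask is not binary", call. = FALSE)
  vol <- array(0L, dim = c(dim(mask$front), 2L))
  vol[, , 1L] <- mask$front
  vol[, , 2L] <- mask$back
  RNifti::writeNifti(RNifti::asNifti(vol), path, datatype = "uint8")
  invisible(path)
}

#' @rdname export_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  vol <- RNifti::readNifti(path)
  vol <- array(as.integer(vol), dim = dim(vol))
  stopifnot(length(dim(vol)) == 3L, dim(vol)[3] == 2L)
  body_map(vol[, , 1L], vol[, , 2L], provenance = list(source = path))
}
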