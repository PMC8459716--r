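#' Controlled vocabularies for findings, symptoms and organs
#'
#' The analysis distinguishes three kinds of clinical findings:
#' *distributed* findings drawn on the body template (including spontaneous
#' pain), *lateralized* findings recorded only as a side label, and *other*
#' findings (segmental symptoms of viscero-visceral reflexes) recorded as
#' binary flags.
#'
#' @return A character vector of valid tokens.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
distributed_signs <- function() {
  c("spontaneous_pain", "allodynia", "superficial_hyperalgesia",
    "deep_hyperalgesia", "superficial_skin_resistance", "muscle_resistance",
    "defense", "asymmetric_hyperhidrosis", "piloerection",
    "vasomotor_changes", "zoster", "passive_movement_resistance")
}

#' @rdname vocabulary
#' @export
lateralized_findings <- function() {
  c("mydriasis", "glossy_eye", "eyelid_separation", "tense_facial_muscles",
    "asymmetric_posture", "reduced_respiration")
}

#' @rdname vocabulary
#' @export
segmental_symptoms <- function() {
  c("nausea", "vomiting", "constipation", "diarrhea", "meteorism",
    "urinary_retention")
}

#' @rdname vocabulary
#' @export
organ_groups <- function() {
  c("heart", "lungs", "stomach", "liver_gallbladder", "kidneys_ureters",
    "other", "multi", "undiagnosed")
}

#' @rdname vocabulary
#' @export
analyzable_organs <- function() {
  c("heart", "lungs", "stomach", "liver_gallbladder", "kidneys_ureters")
}

# Ipsilateral side per organ under the side rule: signs from the heart and
# stomach predominate on the left, from liver/gallbladder on the right.
# Paired organs (lungs, kidneys/ureters) have no fixed side.
ipsilateral_side_of <- function(organ) {
  switch(organ,
    heart = "left",
    stomach = "left",
    liver_gallbladder = "right",
    lungs = NA_character_,
    kidneys_ureters = NA_character_,
    NA_character_)
}

body_sides <- function() c("left", "right")
body_views <- function() c("front", "back")

# Round half away from zero, the convention used for all printed percentages.
round_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
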