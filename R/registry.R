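#' Syndrome-element registry
#'
#' The 47 syndrome elements used throughout the package, organised into the
#' four differentiation groups of TCM inquiry diagnostics:
#' eight-principle (indices 1--8), qi--blood--fluid--humor (9--24),
#' disease-cause (25--31) and visceral (32--47).
#'
#' Elements 7 ("Deficiency") and 8 ("Excess") are composite principles that
#' are not scored directly from questionnaire answers; they are present in the
#' registry but excluded from the evaluable set used by value-order
#' assignment and matched-degree evaluation, leaving 45 evaluable elements
#' (6 / 7 / 16 / 16 per group).
#'
#' @return A data.frame with one row per element and columns
#'   `index` (integer 1..47), `name` (element name), `label` (short label
#'   `e<index>` used in contexts and diagrams), `group` (factor with levels
#'   `eight_principle`, `disease_cause`, `qi_blood_fluid_humor`, `visceral`)
#'   and `evaluable` (logical; FALSE only for indices 7 and 8).
#' @examples
#' reg <- load_registry()
#' table(reg$group)
#' sum(reg$evaluable)  # 45
#' @export
load_registry <- function() {
  names47 <- c(
    "Yang deficiency", "Yin deficiency", "Yang hyperactivity", "Yang floating",
    "Exterior", "Half-exterior half-interior", "Deficiency", "Excess",
    "Qi deficiency", "Qi stagnation", "Qi sinking", "Insecurity of qi",
    "Qi counterflow", "Blood deficiency", "Blood stasis", "Blood heat",
    "Blood cold", "Stirring blood", "Stirring wind", "Phlegm",
    "Retained fluid", "Water retention", "Fluid depletion", "Essence deficiency",
    "External wind", "Cold", "Summerheat", "Dampness", "Dryness", "Fire-heat",
    "Food accumulation",
    "Liver", "Gallbladder", "Lung", "Large intestine", "Spleen", "Stomach",
    "Kidney", "Bladder", "Heart", "Small intestine", "Heart spirit",
    "Chest and diaphragm", "Uterus", "Sinew and bone", "Skin",
    "Meridian-collateral"
  )
  group <- character(47L)
  group[1:8]   <- "eight_principle"
  group[9:24]  <- "qi_blood_fluid_humor"
  group[25:31] <- "disease_cause"
  group[32:47] <- "visceral"
  reg <- data.frame(
    index = 1:47,
    name = names47,
    label = paste0("e", 1:47),
    group = factor(group, levels = c(
      "eight_principle", "disease_cause", "qi_blood_fluid_humor", "visceral"
    )),
    evaluable = !(1:47 %in% c(7L, 8L)),
    stringsAsFactors = FALSE
  )
  class(reg) <- c("element_registry", "data.frame")
  reg
}

#' Answer-level weights
#'
#' Maps the four categorical inquiry answer levels to numeric weights:
#' A (severe / always) -> 1, B (a little severe / sometimes) -> 0.618,
#' C (not severe / seldom) -> 0.382, D (none / never) -> 0.
#'
#' @param label Character vector of answer labels in `{"A","B","C","D"}`.
#'   `NA` entries (questions not applicable to the respondent's sex) map to
#'   weight 0.
#' @return Numeric vector of weights, same length as `label`.
#' @examples
#' answer_weight(c("A", "B", "C", "D"))
#' @export
answer_weight <- function(label) {
  w <- c(A = 1, B = 0.618, C = 0.382, D = 0)
  bad <- !is.na(label) & !(label %in% names(w))
  if (any(bad)) {
    stop("unknown answer label(s): ",
         paste(unique(label[bad]), collapse = ", "),
         " (expected A, B, C or D)", call. = FALSE)
  }
  out <- unname(w[label])
  out[is.na(label)] <- 0
  out
}

#' Default questionnaire layout
#'
#' The inquiry questionnaire comprises 194 questions; questions 1--177 apply
#' to both sexes and 178--194 to females only, so a male respondent answers
#' 177 questions and a female respondent 194. Question texts are not part of
#' the engine; only ids and sex applicability are modelled.
#'
#' @return A data.frame with columns `question_id` (integer) and
#'   `sex_applicability` (`"both"` or `"female"`).
#' @examples
#' q <- default_questionnaire()
#' length(questionnaire_ids(q, "male"))   # 177
#' length(questionnaire_ids(q, "female")) # 194
#' @export
default_questionnaire <- function() {
  data.frame(
    question_id = 1:194,
    sex_applicability = c(rep("both", 177L), rep("female", 17L)),
    stringsAsFactors = FALSE
  )
}

#' Question ids applicable to a sex
#'
#' @param questionnaire A questionnaire data.frame as from
#'   [default_questionnaire()].
#' @param sex `"male"` or `"female"`.
#' @return Integer vector of applicable question ids.
#' @export
questionnaire_ids <- function(questionnaire, sex) {
  sex <- match.arg(sex, c("male", "female"))
  keep <- questionnaire$sex_applicability == "both" |
    questionnaire$sex_applicability == sex
  questionnaire$question_id[keep]
}

# Per-group evaluable element indices, in registry order.
evaluable_groups <- function(registry = load_registry()) {
  ev <- registry[registry$evaluable, ]
  split(ev$index, ev$group)
}
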