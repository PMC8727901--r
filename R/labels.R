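#' Entity label inventory
#'
#' The annotation scheme uses 12 entity labels: 10 semantic roles describing
#' the parts a span plays in a chemical reaction (the example heading
#' identifier, starting material, reagent/catalyst, product, solvent, time,
#' temperature, yields and other compounds) and 2 event-trigger types for the
#' verbs/nominalizations that denote a synthesis step (`REACTION_STEP`) or a
#' post-reaction workup step (`WORKUP`).
#'
#' @return `entityLabels()` returns all 12 labels; `roleLabels()` the 10
#'   semantic roles; `triggerLabels()` the 2 trigger types.
#' @examples
#' entityLabels()
#' isTrigger("WORKUP")
#' @export
entityLabels <- function() c(roleLabels(), triggerLabels())

#' @rdname entityLabels
#' @export
roleLabels <- function() {
  c("EXAMPLE_LABEL", "STARTING_MATERIAL", "REAGENT_CATALYST",
    "REACTION_PRODUCT", "SOLVENT", "TIME", "TEMPERATURE",
    "YIELD_PERCENT", "YIELD_OTHER", "OTHER_COMPOUND")
}

#' @rdname entityLabels
#' @export
triggerLabels <- function() c("REACTION_STEP", "WORKUP")

#' @param label character vector of label names.
#' @rdname entityLabels
#' @export
isTrigger <- function(label) label %in% triggerLabels()

# Roles taking the compound-argument relation (ARG1) vs the auxiliary
# relation (ARGM). EXAMPLE_LABEL is never a relation argument.
arg1Roles <- function() {
  c("STARTING_MATERIAL", "REAGENT_CATALYST", "REACTION_PRODUCT",
    "SOLVENT", "OTHER_COMPOUND")
}

argmRoles <- function() c("TIME", "TEMPERATURE", "YIELD_OTHER", "YIELD_PERCENT")

#' Relation label for a trigger/role pair
#'
#' The relation type is fully determined by the argument's role: auxiliary
#' arguments (time, temperature, yields) take `ARGM`, compound arguments take
#' `ARG1`. The example-heading identifier is never a relation argument.
#'
#' @param triggerLabel a trigger label (`REACTION_STEP` or `WORKUP`).
#' @param argumentLabel a semantic role label other than `EXAMPLE_LABEL`.
#' @return `"ARG1"` or `"ARGM"` (vectorized over `argumentLabel`).
#' @examples
#' assignRelationLabel("REACTION_STEP", "SOLVENT")   # ARG1
#' assignRelationLabel("WORKUP", "TIME")             # ARGM
#' @export
assignRelationLabel <- function(triggerLabel, argumentLabel) {
  if (!all(isTrigger(triggerLabel)))
    stop("triggerLabel must be a trigger type: ",
         paste(setdiff(triggerLabel, triggerLabels()), collapse = ", "))
  bad <- !argumentLabel %in% c(arg1Roles(), argmRoles())
  if (any(bad))
    stop("argumentLabel must be a semantic role other than EXAMPLE_LABEL, got: ",
         paste(unique(argumentLabel[bad]), collapse = ", "))
  ifelse(argumentLabel %in% argmRoles(), "ARGM", "ARG1")
}

# Legacy spellings accepted on input, normalized to the canonical forms.
normalizeLabel <- function(label) {
  alias <- c(REACTION_SETUP = "REACTION_STEP", WORK_UP = "WORKUP")
  out <- ifelse(label %in% names(alias), alias[label], label)
  unname(out)
}
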