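#' The seven-state childcare alphabet
#'
#' Main childcare provision at each survey sweep is coded into seven core
#' categories: private group childcare (e.g. private nurseries), local
#' authority or community group childcare, single-professional care
#' (childminders, nannies), informal care by family or friends, informal
#' grandparent care, any other arrangement, and none (parental care only).
#'
#' @param states Optional character vector of state codes; defaults to the
#'   seven core categories.
#' @param labels Display labels, same length as `states`.
#' @param colors Plotting colours, same length as `states`.
#' @return An object of class `care_alphabet`: a data frame with columns
#'   `state`, `label`, `color`.
#' @export
state_alphabet <- function(states = NULL, labels = NULL, colors = NULL) {
  if (is.null(states)) {
    states <- c("PrivateGroup", "LAGroup", "SingleProfessional",
                "FamilyFriends", "Grandparent", "Other", "None")
    labels <- c("Private group childcare",
                "Local authority / community group childcare",
                "Single professional care",
                "Family or friends informal care",
                "Grandparent informal care",
                "Any other",
                "None (parental care only)")
    colors <- c("#e78ac3", "#ffd92f", "#a6761d",
                "#66c2a5", "#fc8d62", "#999999", "#8da0cb")
  }
  if (anyDuplicated(states)) stop("alphabet state codes must be unique")
  if (length(states) < 2L) stop("alphabet must contain at least two states")
  if (is.null(labels)) labels <- states
  if (is.null(colors)) colors <- grDevices::hcl.colors(length(states), "Dark 3")
  stopifnot(length(labels) == length(states), length(colors) == length(states))
  out <- data.frame(state = states, label = labels, color = colors,
                    stringsAsFactors = FALSE)
  class(out) <- c("care_alphabet", "data.frame")
  out
}

#' @export
print.care_alphabet <- function(x, ...) {
  cat("Childcare state alphabet (", nrow(x), " states)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

## Canonical factor levels used throughout the package.
.educ_levels <- c("Degree", "Highers", "UpperStdGrades", "LowerStdGradesNone")
.educ_labels <- c("Degree", "Highers", "Upper Level Standard Grades",
                  "Lower Level Standard Grades or none")

.typ_levels <- c("ParentsFamilyFriends", "Grandparents", "PrivateGroup",
                 "SingleProfessional")
.typ_labels <- c("Parents, friends & family", "Grandparents",
                 "Private Group Childcare", "Single Professional Care")

#' Education and typology level codes
#'
#' Convenience accessors for the four maternal-education levels (the
#' exposure, highest first) and the four childcare typology names (the
#' mediator, reference first).
#'
#' @return Character vector of level codes.
#' @export
education_levels <- function() .educ_levels

#' @rdname education_levels
#' @export
typology_levels <- function() .typ_levels
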