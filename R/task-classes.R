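#' Task classes for the eight-direction isometric protocol
#'
#' The protocol tests maximal isometric torque in eight directions at the
#' shoulder and elbow: elbow flexion (EF) / extension (EE), shoulder
#' abduction (AB) / adduction (AD), external (ER) / internal (IR) rotation,
#' and horizontal abduction (HAB) / adduction (HAD). Each direction is the
#' positive or negative side of one of four torque degrees of freedom, and
#' belongs to one of the two classic post-stroke synergy groups: the flexion
#' synergy couples EF, AB, ER and HAB; the extension synergy couples EE, AD,
#' IR and HAD.
#'
#' Class order follows the convention used for confusion-matrix reporting:
#' the four flexion-synergy classes first, then the four extension-synergy
#' classes, so within-synergy confusions appear in diagonal blocks.
#'
#' @return A data frame with one row per class and columns `code`,
#'   `synergy_group`, `primary_axis` (index into the 4-DOF torque vector,
#'   ordered AB/AD, HAB/HAD, ER/IR, EF/EE) and `primary_sign` (+1 for the
#'   first-named direction of each axis: AB, HAB, ER, EF).
#' @examples
#' task_classes()
#' @export
task_classes <- function() {
  data.frame(
    code = c("EF", "AB", "ER", "HAB", "EE", "AD", "IR", "HAD"),
    synergy_group = rep(c("flexion", "extension"), each = 4L),
    primary_axis = c(4L, 1L, 3L, 2L, 4L, 1L, 3L, 2L),
    primary_sign = c(1, 1, 1, 1, -1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Canonical class order for reporting
#'
#' @return Character vector of the 8 class codes in reporting order
#'   (flexion-synergy block then extension-synergy block).
#' @export
class_order <- function() task_classes()$code

#' Names of the four torque degrees of freedom
#'
#' Order matches `primary_axis` in [task_classes()]: shoulder
#' abduction/adduction, horizontal abduction/adduction, external/internal
#' rotation, elbow flexion/extension. Positive torque is the first-named
#' direction.
#'
#' @return Character vector of length 4.
#' @export
torque_dof_names <- function() c("abad", "habhad", "erir", "efee")

# Look up one class row; errors on unknown codes.
class_info <- function(code) {
  tc <- task_classes()
  i <- match(code, tc$code)
  if (anyNA(i)) {
    stop("unknown task class: ", paste(code[is.na(i)], collapse = ", "))
  }
  tc[i, , drop = FALSE]
}
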