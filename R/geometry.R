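#' Rigid-body geometry linking the load cell to the joint centres
#'
#' The load cell measures three forces and three moments at its own origin,
#' in its own frame. Joint torques are obtained by translating the measured
#' wrench to each joint centre and rotating it into the anatomical frame:
#' for a joint with lever arm `r` (metres, load-cell origin to joint centre,
#' expressed in the load-cell frame) the anatomical joint moment is
#' `rotation %*% (M + r x F)` per sample. The three shoulder torque DOFs
#' (AB/AD, HAB/HAD, ER/IR) are read from components of the shoulder moment,
#' and elbow flexion/extension from a component of the elbow moment; the
#' `axis_map` records which component, at which joint, with which sign.
#'
#' The default geometry places the arm in the transverse plane at shoulder
#' height (90 degrees abduction, 90 degrees elbow flexion) with the forearm
#' cast to the load cell: anatomical x points forward (sagittal axis), y
#' along the humerus, z up. Abduction/adduction is the moment about x,
#' external/internal rotation about the humeral long axis y, horizontal
#' ab/adduction about z at the shoulder, and elbow flexion/extension about
#' z at the elbow.
#'
#' @param rotation 3x3 orthonormal rotation (load-cell frame to anatomical
#'   frame), determinant +1.
#' @param lever_shoulder,lever_elbow Numeric length-3 lever arms in metres
#'   from the load-cell origin to the shoulder and elbow joint centres.
#' @param axis_map Data frame with columns `dof` (the four names from
#'   [torque_dof_names()], each exactly once), `joint` ("shoulder" or
#'   "elbow"), `component` (1-3, component of that joint's anatomical
#'   moment) and `sign` (+1 or -1).
#' @return An object of class `"rigid_body_geometry"`.
#' @examples
#' geom <- rigid_body_geometry()
#' geom$axis_map
#' @export
rigid_body_geometry <- function(rotation = diag(3),
                                lever_shoulder = c(0.25, 0.30, 0),
                                lever_elbow = c(0.25, 0, 0),
                                axis_map = default_axis_map()) {
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10) {
    stop("rotation must be orthonormal (R'R = I within 1e-10)")
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be proper (determinant +1)")
  }
  stopifnot(length(lever_shoulder) == 3L, length(lever_elbow) == 3L,
            all(is.finite(lever_shoulder)), all(is.finite(lever_elbow)))
  need <- c("dof", "joint", "component", "sign")
  if (!is.data.frame(axis_map) || !all(need %in% names(axis_map))) {
    stop("axis_map must be a data frame with columns dof, joint, component, sign")
  }
  if (!setequal(axis_map$dof, torque_dof_names()) ||
      nrow(axis_map) != 4L || anyDuplicated(axis_map$dof)) {
    stop("axis_map must cover each of the 4 torque DOFs exactly once")
  }
  if (!all(axis_map$joint %in% c("shoulder", "elbow"))) {
    stop("axis_map joint must be 'shoulder' or 'elbow'")
  }
  if (!all(axis_map$component %in% 1:3) || !all(axis_map$sign %in% c(-1, 1))) {
    stop("axis_map component must be in 1..3 and sign in {-1, +1}")
  }
  structure(
    list(rotation = rotation,
         lever_shoulder = as.numeric(lever_shoulder),
         lever_elbow = as.numeric(lever_elbow),
         axis_map = axis_map[match(torque_dof_names(), axis_map$dof), ,
                             drop = FALSE]),
    class = "rigid_body_geometry"
  )
}

#' Default assignment of anatomical moment components to torque DOFs
#'
#' @return Data frame usable as the `axis_map` of [rigid_body_geometry()].
#' @export
default_axis_map <- function() {
  data.frame(
    dof = c("abad", "habhad", "erir", "efee"),
    joint = c("shoulder", "shoulder", "shoulder", "elbow"),
    component = c(1L, 3L, 2L, 3L),
    sign = c(1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

# Row-wise cross product r x F for an n x 3 matrix of forces.
cross_rows <- function(r, F) {
  cbind(r[2] * F[, 3] - r[3] * F[, 2],
        r[3] * F[, 1] - r[1] * F[, 3],
        r[1] * F[, 2] - r[2] * F[, 1])
}

#' Convert 6-DOF load-cell data to 4-DOF joint torques
#'
#' Applies, per sample, the rigid-body transform
#' `rotation %*% (M + lever x F)` at the shoulder and at the elbow, and
#' reads the four torque DOFs off the mapped anatomical moment components
#' with their mapped signs. Positive torque is abduction, horizontal
#' abduction, external rotation and elbow flexion.
#'
#' @param loadcell Numeric matrix with 6 columns (Fx, Fy, Fz in N; Mx, My,
#'   Mz in N m), one row per sample.
#' @param geometry A [rigid_body_geometry()].
#' @param fs Sampling rate in Hz, stored on the result.
#' @return An object of class `"joint_torque_series"`: a list with `torque`
#'   (n x 4 matrix, columns [torque_dof_names()]) and `fs`.
#' @examples
#' lc <- matrix(rep(c(0, 0, 10, 0, 0, 0), each = 5), ncol = 6)
#' compute_joint_torques(lc, rigid_body_geometry(), fs = 1000)
#' @export
compute_joint_torques <- function(loadcell, geometry = rigid_body_geometry(),
                                  fs = 1000) {
  loadcell <- as.matrix(loadcell)
  if (ncol(loadcell) != 6L) {
    stop("loadcell must have 6 channels (Fx, Fy, Fz, Mx, My, Mz)")
  }
  if (!all(is.finite(loadcell))) stop("loadcell contains non-finite values")
  if (!inherits(geometry, "rigid_body_geometry")) {
    geometry <- do.call(rigid_body_geometry, as.list(geometry))
  }
  F <- loadcell[, 1:3, drop = FALSE]
  M <- loadcell[, 4:6, drop = FALSE]
  anat <- list(
    shoulder = (M + cross_rows(geometry$lever_shoulder, F)) %*%
      t(geometry$rotation),
    elbow = (M + cross_rows(geometry$lever_elbow, F)) %*%
      t(geometry$rotation)
  )
  am <- geometry$axis_map
  torque <- matrix(0, nrow(loadcell), 4L,
                   dimnames = list(NULL, torque_dof_names()))
  for (k in seq_len(4L)) {
    torque[, k] <- am$sign[k] * anat[[am$joint[k]]][, am$component[k]]
  }
  structure(list(torque = torque, fs = fs), class = "joint_torque_series")
}

# Inverse of compute_joint_torques used by the trial generator: build a
# 6-channel load-cell series whose forward transform reproduces a given
# 4-DOF torque series exactly. Requires the standard axis_map structure
# (three DOFs on the shoulder covering three distinct components, one on
# the elbow) and a nonzero shoulder-elbow offset.
invert_joint_torques <- function(torque, geometry = rigid_body_geometry()) {
  torque <- as.matrix(torque)
  stopifnot(ncol(torque) == 4L)
  am <- geometry$axis_map
  sh <- am[am$joint == "shoulder", , drop = FALSE]
  el <- am[am$joint == "elbow", , drop = FALSE]
  if (nrow(sh) != 3L || nrow(el) != 1L || anyDuplicated(sh$component)) {
    stop("inverse transform needs 3 distinct shoulder components and 1 elbow DOF")
  }
  n <- nrow(torque)
  # anatomical shoulder moment fixed by the three shoulder DOFs
  anat_s <- matrix(0, n, 3L)
  for (i in seq_len(3L)) {
    k <- match(sh$dof[i], torque_dof_names())
    anat_s[, sh$component[i]] <- sh$sign[i] * torque[, k]
  }
  # choose F so the elbow moment component matches the elbow DOF:
  # anat_e[j] = anat_s[j] - (u_j x d) . F  with d = lever_s - lever_e
  d <- geometry$lever_shoulder - geometry$lever_elbow
  u <- geometry$rotation[el$component, ]
  w <- c(u[2] * d[3] - u[3] * d[2],
         u[3] * d[1] - u[1] * d[3],
         u[1] * d[2] - u[2] * d[1])
  if (sum(w^2) < 1e-12) {
    stop("degenerate geometry: elbow axis parallel to shoulder-elbow offset")
  }
  k_el <- match(el$dof, torque_dof_names())
  alpha <- anat_s[, el$component] - el$sign * torque[, k_el]
  F <- outer(alpha / sum(w^2), w)
  M <- anat_s %*% geometry$rotation - cross_rows(geometry$lever_shoulder, F)
  lc <- cbind(F, M)
  colnames(lc) <- c("fx", "fy", "fz", "mx", "my", "mz")
  lc
}

#' @export
print.joint_torque_series <- function(x, ...) {
  cat("Joint torque series:", nrow(x$torque), "samples at", x$fs, "Hz\n")
  cat("DOFs:", paste(colnames(x$torque), collapse = ", "), "\n")
  invisible(x)
}
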