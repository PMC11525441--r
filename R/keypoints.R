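#' Canonical full-body keypoint labels
#'
#' The 23 body segments of the full-body inertial motion-capture model, in
#' canonical order: the spine chain from the pelvis upward, then the right
#' and left arms, then the right and left legs, ending at the left toe.
#' All full-body operations in this package (feature extraction, the
#' synthetic generator, the MVNX-style reader) index keypoints by these
#' labels.
#'
#' @return Character vector of length 23.
#' @export
#' @examples
#' mocap_keypoint_labels()[c(1, 7, 23)]  # "Pelvis" "Head" "Left toe"
mocap_keypoint_labels <- function() {
  c("Pelvis", "L5", "L3", "T12", "T8", "Neck", "Head",
    "Right shoulder", "Right upper arm", "Right forearm", "Right hand",
    "Left shoulder", "Left upper arm", "Left forearm", "Left hand",
    "Right upper leg", "Right lower leg", "Right foot", "Right toe",
    "Left upper leg", "Left lower leg", "Left foot", "Left toe")
}

# Extremity endpoints used by limb contraction: the head plus both hands and
# both toes.
.extremity_labels <- function() {
  c("Right hand", "Left hand", "Right toe", "Left toe")
}

# Parent of each keypoint in the skeleton tree (by label; Pelvis is the root).
# Shoulder segments hang off T8 so the clavicle line sits below the neck.
.skeleton_parents <- function() {
  c("Pelvis" = NA_character_, "L5" = "Pelvis", "L3" = "L5", "T12" = "L3",
    "T8" = "T12", "Neck" = "T8", "Head" = "Neck",
    "Right shoulder" = "T8", "Right upper arm" = "Right shoulder",
    "Right forearm" = "Right upper arm", "Right hand" = "Right forearm",
    "Left shoulder" = "T8", "Left upper arm" = "Left shoulder",
    "Left forearm" = "Left upper arm", "Left hand" = "Left forearm",
    "Right upper leg" = "Pelvis", "Right lower leg" = "Right upper leg",
    "Right foot" = "Right lower leg", "Right toe" = "Right foot",
    "Left upper leg" = "Pelvis", "Left lower leg" = "Left upper leg",
    "Left foot" = "Left lower leg", "Left toe" = "Left foot")
}

# Skeleton edges as a 2-column matrix of keypoint indices (child, parent),
# used for bone-length checks and silhouette rasterization.
.skeleton_edges <- function() {
  labels <- mocap_keypoint_labels()
  parents <- .skeleton_parents()
  child <- names(parents)[!is.na(parents)]
  cbind(match(child, labels), match(parents[child], labels))
}
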