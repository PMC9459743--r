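# Azure Kinect body-tracking joint set and TUG class/event vocabularies.

#' The 32 Azure Kinect body-tracking joints
#'
#' Returns the joint names of the Azure Kinect body-tracking SDK in its
#' canonical order. Skeleton CSV columns are named `<JOINT>_x`, `<JOINT>_y`,
#' `<JOINT>_z` with these joint names.
#'
#' @return Character vector of length 32.
#' @export
#' @examples
#' azure_kinect_joints()[1:3]
azure_kinect_joints <- function() {
  c(
    "PELVIS", "SPINE_NAVAL", "SPINE_CHEST", "NECK",
    "CLAVICLE_LEFT", "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
    "HAND_LEFT", "HANDTIP_LEFT", "THUMB_LEFT",
    "CLAVICLE_RIGHT", "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
    "HAND_RIGHT", "HANDTIP_RIGHT", "THUMB_RIGHT",
    "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
    "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT",
    "HEAD", "NOSE", "EYE_LEFT", "EAR_LEFT", "EYE_RIGHT", "EAR_RIGHT"
  )
}

#' TUG subtask classes
#'
#' The five frame-level classes predicted by the model. The outbound walk and
#' the walk back share the single `walk` class; the canonical template (see
#' [tug_template()]) distinguishes them positionally.
#'
#' @return Character vector of length 5, in template order of first appearance.
#' @export
tug_classes <- function() {
  c("sit", "sit_to_stand", "walk", "turn", "stand_to_sit")
}

#' Canonical TUG subtask template
#'
#' The strict subtask order of a TUG trial: sit, sit-to-stand, walk, turn,
#' walk back, stand-to-sit, sit. Walk and walk back carry the same class
#' label; the leading and trailing sit segments may be empty in degenerate
#' recordings, the five active segments may not.
#'
#' @return Character vector of length 7 of class names.
#' @export
tug_template <- function() {
  c("sit", "sit_to_stand", "walk", "turn", "walk", "stand_to_sit", "sit")
}

#' The six TUG event names
#'
#' Events separating consecutive subtasks, with their conventional integer
#' labels 0 to 5: StartMove (trunk tilted 45 degrees rising from the chair),
#' StartWalk (first step off the ground), StartTurn, EndTurn, StartSit and
#' EndSit (trunk tilted 45 degrees leaning back into the chair).
#'
#' @return Character vector of length 6.
#' @export
tug_event_names <- function() {
  c("StartMove", "StartWalk", "StartTurn", "EndTurn", "StartSit", "EndSit")
}

# groups recognised by the simulator and trial metadata
tug_groups <- function() c("healthy_young", "older_adult", "stroke")
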