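# COCO 17-keypoint layout (2D pose estimation, sagittal view).
# Channel 1 = x (horizontal; also the walking direction in a side view),
# channel 2 = y (vertical). Mirroring negates x and swaps left/right joints,
# which in a side view corresponds to reversing the walking direction.
name: coco17
format_version: 1
channels: ["x", "y"]
lateral_channel: 1
vertical_channel: 2
forward_channel: 1
fps_default: 30
center_joints: [11, 12]
torso_from: [11, 12]
torso_to: [5, 6]
measure_joints:
  left_ankle: 15
  right_ankle: 16
joints:
  - {id: 0,  name: nose,           side: C, part: head, swing: 0.0,  pose: [ 0.00, 1.60]}
  - {id: 1,  name: left_eye,       side: L, part: head, swing: 0.0,  pose: [-0.03, 1.63]}
  - {id: 2,  name: right_eye,      side: R, part: head, swing: 0.0,  pose: [ 0.03, 1.63]}
  - {id: 3,  name: left_ear,       side: L, part: head, swing: 0.0,  pose: [-0.07, 1.60]}
  - {id: 4,  name: right_ear,      side: R, part: head, swing: 0.0,  pose: [ 0.07, 1.60]}
  - {id: 5,  name: left_shoulder,  side: L, part: arm,  swing: 0.10, pose: [-0.20, 1.45]}
  - {id: 6,  name: right_shoulder, side: R, part: arm,  swing: 0.10, pose: [ 0.20, 1.45]}
  - {id: 7,  name: left_elbow,     side: L, part: arm,  swing: 0.50, pose: [-0.25, 1.20]}
  - {id: 8,  name: right_elbow,    side: R, part: arm,  swing: 0.50, pose: [ 0.25, 1.20]}
  - {id: 9,  name: left_wrist,     side: L, part: arm,  swing: 1.00, pose: [-0.28, 0.95]}
  - {id: 10, name: right_wrist,    side: R, part: arm,  swing: 1.00, pose: [ 0.28, 0.95]}
  - {id: 11, name: left_hip,       side: L, part: leg,  swing: 0.15, pose: [-0.10, 0.95]}
  - {id: 12, name: right_hip,      side: R, part: leg,  swing: 0.15, pose: [ 0.10, 0.95]}
  - {id: 13, name: left_knee,      side: L, part: leg,  swing: 0.50, pose: [-0.10, 0.50]}
  - {id: 14, name: right_knee,     side: R, part: leg,  swing: 0.50, pose: [ 0.10, 0.50]}
  - {id: 15, name: left_ankle,     side: L, part: leg,  swing: 1.00, pose: [-0.10, 0.10]}
  - {id: 16, name: right_ankle,    side: R, part: leg,  swing: 1.00, pose: [ 0.10, 0.10]}
edges:
  - [0, 1]
  - [0, 2]
  - [1, 3]
  - [2, 4]
  - [3, 5]
  - [4, 6]
  - [5, 6]
  - [5, 7]
  - [7, 9]
  - [6, 8]
  - [8, 10]
  - [5, 11]
  - [6, 12]
  - [11, 12]
  - [11, 13]
  - [13, 15]
  - [12, 14]
  - [14, 16]
mirror_pairs:
  - [1, 2]
  - [3, 4]
  - [5, 6]
  - [7, 8]
  - [9, 10]
  - [11, 12]
  - [13, 14]
  - [15, 16]
partition:
  half:
    upper: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
    lower: [11, 12, 13, 14, 15, 16]
  limb:
    left_arm: [5, 7, 9]
    right_arm: [6, 8, 10]
    left_leg: [11, 13, 15]
    right_leg: [12, 14, 16]
    torso: [0, 1, 2, 3, 4, 5, 6, 11, 12]
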