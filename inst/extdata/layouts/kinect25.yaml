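# Kinect V2 25-joint skeleton layout.
# Joint indices are 0-based. Coordinates are metres in a body-centred frame:
# channel 1 = x (lateral, left side negative), 2 = y (vertical, up),
# 3 = z (anterior/walking direction). `pose` is the neutral standing pose used
# by the synthetic gait generator; `swing` is the relative gait-oscillation
# weight of the joint (distal joints swing more); `side` is L/R/C.
name: kinect25
format_version: 1
channels: ["x", "y", "z"]
lateral_channel: 1
vertical_channel: 2
forward_channel: 3
fps_default: 30
center_joints: [0]
torso_from: [0]
torso_to: [20]
measure_joints:
  left_ankle: 14
  right_ankle: 18
joints:
  - {id: 0,  name: spine_base,     side: C, part: torso, swing: 0.0,  pose: [ 0.00, 1.00, 0.00]}
  - {id: 1,  name: spine_mid,      side: C, part: torso, swing: 0.0,  pose: [ 0.00, 1.25, 0.00]}
  - {id: 2,  name: neck,           side: C, part: torso, swing: 0.0,  pose: [ 0.00, 1.50, 0.00]}
  - {id: 3,  name: head,           side: C, part: head,  swing: 0.0,  pose: [ 0.00, 1.65, 0.00]}
  - {id: 4,  name: shoulder_left,  side: L, part: arm,   swing: 0.10, pose: [-0.20, 1.45, 0.00]}
  - {id: 5,  name: elbow_left,     side: L, part: arm,   swing: 0.50, pose: [-0.25, 1.20, 0.00]}
  - {id: 6,  name: wrist_left,     side: L, part: arm,   swing: 0.85, pose: [-0.28, 0.95, 0.00]}
  - {id: 7,  name: hand_left,      side: L, part: arm,   swing: 1.00, pose: [-0.30, 0.85, 0.00]}
  - {id: 8,  name: shoulder_right, side: R, part: arm,   swing: 0.10, pose: [ 0.20, 1.45, 0.00]}
  - {id: 9,  name: elbow_right,    side: R, part: arm,   swing: 0.50, pose: [ 0.25, 1.20, 0.00]}
  - {id: 10, name: wrist_right,    side: R, part: arm,   swing: 0.85, pose: [ 0.28, 0.95, 0.00]}
  - {id: 11, name: hand_right,     side: R, part: arm,   swing: 1.00, pose: [ 0.30, 0.85, 0.00]}
  - {id: 12, name: hip_left,       side: L, part: leg,   swing: 0.15, pose: [-0.10, 0.95, 0.00]}
  - {id: 13, name: knee_left,      side: L, part: leg,   swing: 0.50, pose: [-0.10, 0.50, 0.00]}
  - {id: 14, name: ankle_left,     side: L, part: leg,   swing: 1.00, pose: [-0.10, 0.10, 0.00]}
  - {id: 15, name: foot_left,      side: L, part: leg,   swing: 1.10, pose: [-0.10, 0.05, 0.12]}
  - {id: 16, name: hip_right,      side: R, part: leg,   swing: 0.15, pose: [ 0.10, 0.95, 0.00]}
  - {id: 17, name: knee_right,     side: R, part: leg,   swing: 0.50, pose: [ 0.10, 0.50, 0.00]}
  - {id: 18, name: ankle_right,    side: R, part: leg,   swing: 1.00, pose: [ 0.10, 0.10, 0.00]}
  - {id: 19, name: foot_right,     side: R, part: leg,   swing: 1.10, pose: [ 0.10, 0.05, 0.12]}
  - {id: 20, name: spine_shoulder, side: C, part: torso, swing: 0.0,  pose: [ 0.00, 1.45, 0.00]}
  - {id: 21, name: hand_tip_left,  side: L, part: arm,   swing: 1.05, pose: [-0.30, 0.78, 0.00]}
  - {id: 22, name: thumb_left,     side: L, part: arm,   swing: 0.95, pose: [-0.27, 0.82, 0.00]}
  - {id: 23, name: hand_tip_right, side: R, part: arm,   swing: 1.05, pose: [ 0.30, 0.78, 0.00]}
  - {id: 24, name: thumb_right,    side: R, part: arm,   swing: 0.95, pose: [ 0.27, 0.82, 0.00]}
edges:
  - [0, 1]
  - [1, 20]
  - [20, 2]
  - [2, 3]
  - [20, 4]
  - [4, 5]
  - [5, 6]
  - [6, 7]
  - [7, 21]
  - [7, 22]
  - [20, 8]
  - [8, 9]
  - [9, 10]
  - [10, 11]
  - [11, 23]
  - [11, 24]
  - [0, 12]
  - [12, 13]
  - [13, 14]
  - [14, 15]
  - [0, 16]
  - [16, 17]
  - [17, 18]
  - [18, 19]
mirror_pairs:
  - [4, 8]
  - [5, 9]
  - [6, 10]
  - [7, 11]
  - [12, 16]
  - [13, 17]
  - [14, 18]
  - [15, 19]
  - [21, 23]
  - [22, 24]
partition:
  half:
    upper: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 20, 21, 22, 23, 24]
    lower: [0, 12, 13, 14, 15, 16, 17, 18, 19]
  limb:
    left_arm: [4, 5, 6, 7, 21, 22]
    right_arm: [8, 9, 10, 11, 23, 24]
    left_leg: [12, 13, 14, 15]
    right_leg: [16, 17, 18, 19]
    torso: [0, 1, 2, 3, 20]
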