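task:
  states:
  - state_id: START
    duration: 1.0
    successors:
    - state_id: TGT_INFO
      prob: 0.333333333333333
    - state_id: TGT_RAND
      prob: 0.333333333333333
    - state_id: CHOICE
      prob: 0.333333333333333
  - state_id: TGT_INFO
    duration: 1.0
    successors:
    - state_id: CUE_LARGE
      prob: 0.5
    - state_id: CUE_SMALL
      prob: 0.5
  - state_id: TGT_RAND
    duration: 1.0
    successors:
    - state_id: CUE_RAND_A
      prob: 0.5
    - state_id: CUE_RAND_B
      prob: 0.5
  - state_id: CHOICE
    duration: 0.0
    successors:
    - state_id: TGT_INFO
    - state_id: TGT_RAND
    is_choice_state: yes
  - state_id: CUE_LARGE
    duration: 2.25
    successors:
    - state_id: END
      prob: 1.0
    reward_on_exit:
      values: 1.0
      probs: 1.0
  - state_id: CUE_SMALL
    duration: 2.25
    successors:
    - state_id: END
      prob: 1.0
    reward_on_exit:
      values: 0.04
      probs: 1.0
  - state_id: CUE_RAND_A
    duration: 2.25
    successors:
    - state_id: END
      prob: 1.0
    reward_on_exit:
      values:
      - 1.0
      - 0.04
      probs:
      - 0.5
      - 0.5
  - state_id: CUE_RAND_B
    duration: 2.25
    successors:
    - state_id: END
      prob: 1.0
    reward_on_exit:
      values:
      - 1.0
      - 0.04
      probs:
      - 0.5
      - 0.5
  - state_id: END
    duration: 0.0
    is_terminal: yes
  trial_types:
  - label: forced_informative
    start_state: TGT_INFO
    prob: 0.333333333333333
  - label: forced_random
    start_state: TGT_RAND
    prob: 0.333333333333333
  - label: free_choice
    start_state: CHOICE
    prob: 0.333333333333333
  q: 0.5
  r_large: 1.0
  r_small: 0.04
  variant_tag: standard
  base_variant: standard
  reversed: no
engagement:
  hazard_family: valence
  param_a: 0.1
  param_b: 0.5
  v_disengaged: 0.0
policy:
  beta: 10.0
  rule: softmax_difference
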