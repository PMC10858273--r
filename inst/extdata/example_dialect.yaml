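# Example schema-dialect mapping: adapts an external trial CSV whose
# columns differ from the canonical schema.  `columns` maps canonical
# names to the file's column names; `values` optionally remaps codes.
columns:
  triad_id: group
  session_index: session
  trial_index: trial
  condition: cond
  left_proposer: prop_l
  right_proposer: prop_r
  responder: resp
  first_side: first
  offer_left: off_l
  offer_right: off_r
  accepted_side: choice
values:
  condition:
    dyad: dyadic
    tri_sim: triadic_simultaneous
    tri_con: triadic_consecutive
  accepted_side:
    L: left
    R: right
    no_choice: none
  first_side:
    L: left
    R: right
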