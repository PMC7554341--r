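# Verification suite for the ER-calcium toy module. The "reservoir can stay
# full with the pumps off" case fails on the calcium_default fixture (whose
# reservoir rule forces SERCA on) and passes on calcium_corrected.
suite:
  name: calcium_module
  model: calcium_corrected
  cases:
    - name: rest_full_reservoir_without_pumping
      context: {IP3R_stim: 0}
      oracle: stable_states
      quantifier: exists
      expect: {Calcium_ER: active, SERCA: inactive}
    - name: no_ip3r_stimulation_calcium_in_er
      context: {IP3R_stim: 0, SERCA_stim: 1}
      oracle: stable_states
      quantifier: all
      expect: {Calcium_ER: active, IP3R1: inactive}
    - name: no_ip3r_stimulation_calcium_in_cytoplasm
      context: {IP3R_stim: 0, SERCA_stim: 1}
      oracle: trap_spaces
      quantifier: all
      expect: {Calcium_ER: active, IP3R1: inactive}
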