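# Lab-specific labels for the Conventional Gait Model foot markers,
# case-insensitive, matched after stripping the L/R side prefix.
# The distal forefoot marker (TOE) is variously documented as sitting on
# the first or the second metatarsal head; both designations are accepted.
HEE: [HEE, HEEL, CAL, CALC, CALCANEUS]
TOE: [TOE, MT1, MT2, DMT1, DMT2, DM1, DM2, META1, META2]
HLX: [HLX, HALLUX, HAL, BIGTOE]
PMT5: [PMT5, MT5, PM5, META5, VMH, D5M]
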