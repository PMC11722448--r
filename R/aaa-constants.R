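# Shared vocabulary of the test battery (loaded before all other files).

DIAGNOSES <- c("HV", "NIND", "OIND", "RRMS", "SPMS", "PPMS", "CIS", "RIS")
SWAY_STANCES <- c("EO-FA", "EO-FT", "EC-FT")
DRIFT_TESTS <- c("drift_left", "drift_right")
ALL_TESTS <- c(SWAY_STANCES, DRIFT_TESTS)
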