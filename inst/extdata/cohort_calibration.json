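{
  "comment": "Calibration for the synthetic bilingual fluency cohort. 'targets' are the published group-by-condition mean correct counts the generator is calibrated to (letter-fluency targets are per-letter means). Structural parameters: p_continue (within-subcategory continuation probability per retrieval attempt), lambda_category / lambda_letter (expected retrieval attempts per 60 s trial), error rates per emitted response (paraphasia splits evenly into one-edit, still creditable, and two-edit forms). Per-condition switch-success probabilities are derived analytically from the targets at load time; condition effects are carried only by switch success and language-error rates.",
  "targets": {
    "BPWA": { "SS": 7.34, "NS-L1": 7.63, "NS-L2": 5.71, "FS": 5.31,
              "LF-L1": 4.01, "LF-L2": 3.02 },
    "HB":   { "SS": 18.05, "NS-L1": 16.68, "NS-L2": 15.50, "FS": 12.64,
              "LF-L1": 13.11, "LF-L2": 10.51 }
  },
  "target_sds": {
    "BPWA": { "SS": 5.10, "NS-L1": 4.52, "NS-L2": 4.87, "FS": 4.25,
              "LF-L1": 3.38, "LF-L2": 3.52 },
    "HB":   { "SS": 6.43, "NS-L1": 6.51, "NS-L2": 5.32, "FS": 5.95,
              "LF-L1": 3.97, "LF-L2": 3.23 }
  },
  "structural": {
    "BPWA": {
      "p_continue": 0.40,
      "lambda_category": 14,
      "lambda_letter": 8,
      "rates": {
        "intrusion": 0.05,
        "repetition": 0.04,
        "paraphasia": 0.04,
        "language_error": { "NS-L1": 0.02, "NS-L2": 0.05, "SS": 0.0,
                            "FS": 0.08, "LF-L1": 0.01, "LF-L2": 0.02 }
      },
      "ability_sd": 1.0,
      "lambda_coupling": 0.35,
      "switch_coupling": 0.5
    },
    "HB": {
      "p_continue": 0.40,
      "lambda_category": 20,
      "lambda_letter": 16,
      "rates": {
        "intrusion": 0.02,
        "repetition": 0.02,
        "paraphasia": 0.01,
        "language_error": { "NS-L1": 0.005, "NS-L2": 0.01, "SS": 0.0,
                            "FS": 0.02, "LF-L1": 0.005, "LF-L2": 0.01 }
      },
      "ability_sd": 1.0,
      "lambda_coupling": 0.35,
      "switch_coupling": 0.5
    }
  },
  "l1_spanish_prop": 0.8,
  "dominance_l1": 0.7,
  "assessment_ability_loading": 0.7
}
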