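{
  "meta": {
    "alpha": 0.05,
    "model": "random",
    "seed": null,
    "version": "0.1.0"
  },
  "outcomes": {
    "FI": {
      "k": 6,
      "pooled": {
        "estimate": -0.00655045483878465,
        "ci_low": -0.514228956884404,
        "ci_high": 0.501128047206835,
        "z": -0.0252889486449445,
        "p": 0.979824488817397,
        "model": "random"
      },
      "heterogeneity": {
        "Q": 8.56005147618093,
        "df": 5,
        "p_Q": 0.12795220899493,
        "I2": 41.5891363046948,
        "tau2": 0.166385163707429
      },
      "bias": {
        "Nfs": 0,
        "n_comparisons": 6,
        "threshold": 40,
        "robust": false,
        "observed_significance": 0.940253614009291,
        "target_significance": 0.05
      },
      "metareg": {
        "strain": {
          "moderator": "strain",
          "k": 6,
          "QM": 0.869510850506897,
          "df_M": 2,
          "p_QM": 0.647422991030168,
          "tau2_resid": 0.295645844681354,
          "tau2_total": 0.166385163707429,
          "I2_resid": 55.7209650375564,
          "R2": 0,
          "grand_mean": -0.00655045483878465
        },
        "leaf_type": {
          "moderator": "leaf_type",
          "k": 6,
          "QM": 0.869510850506898,
          "df_M": 2,
          "p_QM": 0.647422991030168,
          "tau2_resid": 0.295645844681354,
          "tau2_total": 0.166385163707429,
          "I2_resid": 55.7209650375564,
          "R2": 0,
          "grand_mean": -0.00655045483878465
        },
        "microbes": {
          "moderator": "microbes",
          "k": 6,
          "QM": 1.43312950180654,
          "df_M": 3,
          "p_QM": 0.697787695823395,
          "tau2_resid": 0.370250511602038,
          "tau2_total": 0.166385163707429,
          "I2_resid": 61.2506556014979,
          "R2": 0,
          "grand_mean": -0.00655045483878465
        },
        "dose_bin": {
          "moderator": "dose_bin",
          "k": 6,
          "QM": 4.52235853109013,
          "df_M": 2,
          "p_QM": 0.104227500353369,
          "tau2_resid": 0.0308276422204664,
          "tau2_total": 0.166385163707429,
          "I2_resid": 10.4907949348294,
          "R2": 81.4721207506977,
          "grand_mean": -0.00655045483878465
        },
        "phase_bin": {
          "moderator": "phase_bin",
          "k": 6,
          "QM": 1.67980223186669,
          "df_M": 2,
          "p_QM": 0.431753214831968,
          "tau2_resid": 0.213764888806155,
          "tau2_total": 0.166385163707429,
          "I2_resid": 45.8187476154642,
          "R2": 0,
          "grand_mean": -0.00655045483878465
        }
      }
    }
  }
}
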