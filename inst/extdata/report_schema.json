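{
  "type": "object",
  "required": {
    "n": {"type": "integer"},
    "n_coao": {"type": "integer"},
    "prevalence_percent": {"type": "number"},
    "roc": {
      "type": "object",
      "required": {
        "n": {"type": "integer"},
        "n_coao": {"type": "integer"},
        "evaluable": {"type": "boolean"},
        "auc": {"type": "number"},
        "auc_ci_lower": {"type": "number"},
        "auc_ci_upper": {"type": "number"},
        "n_thresholds": {"type": "integer"},
        "cutoffs": {
          "type": "array",
          "items": {
            "type": "object",
            "required": {
              "criterion": {"type": "string"},
              "threshold": {"type": "number"},
              "threshold_percent": {"type": "number"},
              "sensitivity": {"type": "number"},
              "specificity": {"type": "number"},
              "counts": {
                "type": "object",
                "required": {
                  "tp": {"type": "integer"},
                  "fp": {"type": "integer"},
                  "tn": {"type": "integer"},
                  "fn": {"type": "integer"}
                }
              },
              "metrics": {
                "type": "object",
                "required": {
                  "sensitivity": {"type": "object", "required": {"defined": {"type": "boolean"}}, "optional": {"estimate": {"type": "number"}, "ci_lower": {"type": "number"}, "ci_upper": {"type": "number"}}},
                  "specificity": {"type": "object", "required": {"defined": {"type": "boolean"}}, "optional": {"estimate": {"type": "number"}, "ci_lower": {"type": "number"}, "ci_upper": {"type": "number"}}},
                  "npv": {"type": "object", "required": {"defined": {"type": "boolean"}}, "optional": {"estimate": {"type": "number"}, "ci_lower": {"type": "number"}, "ci_upper": {"type": "number"}}},
                  "ppv": {"type": "object", "required": {"defined": {"type": "boolean"}}, "optional": {"estimate": {"type": "number"}, "ci_lower": {"type": "number"}, "ci_upper": {"type": "number"}}}
                }
              }
            }
          }
        }
      }
    },
    "subgroups": {
      "type": "object",
      "required": {
        "early": {
          "type": "object",
          "required": {
            "n": {"type": "integer"},
            "n_coao": {"type": "integer"},
            "evaluable": {"type": "boolean"}
          },
          "optional": {
            "auc": {"type": "number"},
            "auc_ci_lower": {"type": "number"},
            "auc_ci_upper": {"type": "number"},
            "n_thresholds": {"type": "integer"}
          }
        },
        "late": {
          "type": "object",
          "required": {
            "n": {"type": "integer"},
            "n_coao": {"type": "integer"},
            "evaluable": {"type": "boolean"}
          },
          "optional": {
            "auc": {"type": "number"},
            "auc_ci_lower": {"type": "number"},
            "auc_ci_upper": {"type": "number"},
            "n_thresholds": {"type": "integer"}
          }
        }
      }
    },
    "bands": {
      "type": "object",
      "required": {
        "low": {"type": "number"},
        "high": {"type": "number"},
        "bands": {
          "type": "array",
          "items": {
            "type": "object",
            "required": {
              "band": {"type": "string"},
              "n": {"type": "integer"},
              "coao": {"type": "integer"},
              "fraction_percent": {"type": "number"}
            },
            "optional": {
              "coao_rate_percent": {"type": "number"}
            }
          }
        }
      }
    },
    "group_comparisons": {
      "type": "array",
      "items": {
        "type": "object",
        "required": {
          "variable": {"type": "string"},
          "test": {"type": "string"},
          "degenerate": {"type": "boolean"}
        },
        "optional": {
          "statistic": {"type": "number"},
          "p_value": {"type": "number"}
        }
      }
    },
    "probability_summary": {
      "type": "object",
      "required": {
        "coao": {
          "type": "object",
          "required": {
            "mean_percent": {"type": "number"},
            "n": {"type": "integer"}
          },
          "optional": {"sd_percent": {"type": "number"}}
        },
        "no_coao": {
          "type": "object",
          "required": {
            "mean_percent": {"type": "number"},
            "n": {"type": "integer"}
          },
          "optional": {"sd_percent": {"type": "number"}}
        }
      },
      "optional": {"p_value": {"type": "number"}}
    }
  }
}
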