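{
  "scheme_id": "mini-v1",
  "insertion_order": "ABCDEFGHIJKLMNOPQRSTUVWXYZ",
  "chains": {
    "heavy": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60],
      "regions": {
        "FR1": [1, 10],
        "CDR1": [11, 16],
        "FR2": [17, 26],
        "CDR2": [27, 31],
        "FR3": [32, 49],
        "CDR3": [50, 55],
        "FR4": [56, 60]
      },
      "reentry": {
        "CDR1": 14,
        "CDR2": 29,
        "CDR3": 53
      }
    },
    "kappa": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60],
      "regions": {
        "FR1": [1, 10],
        "CDR1": [11, 16],
        "FR2": [17, 26],
        "CDR2": [27, 31],
        "FR3": [32, 49],
        "CDR3": [50, 55],
        "FR4": [56, 60]
      },
      "reentry": {
        "CDR1": 14,
        "CDR2": 29,
        "CDR3": 53
      }
    },
    "lambda": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60],
      "regions": {
        "FR1": [1, 10],
        "CDR1": [11, 16],
        "FR2": [17, 26],
        "CDR2": [27, 31],
        "FR3": [32, 49],
        "CDR3": [50, 55],
        "FR4": [56, 60]
      },
      "reentry": {
        "CDR1": 14,
        "CDR2": 29,
        "CDR3": 53
      }
    },
    "alpha": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60],
      "regions": {
        "FR1": [1, 10],
        "CDR1": [11, 16],
        "FR2": [17, 26],
        "CDR2": [27, 31],
        "FR3": [32, 49],
        "CDR3": [50, 55],
        "FR4": [56, 60]
      },
      "reentry": {
        "CDR1": 14,
        "CDR2": 29,
        "CDR3": 53
      }
    },
    "beta": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60],
      "regions": {
        "FR1": [1, 10],
        "CDR1": [11, 16],
        "FR2": [17, 26],
        "CDR2": [27, 31],
        "FR3": [32, 49],
        "CDR3": [50, 55],
        "FR4": [56, 60]
      },
      "reentry": {
        "CDR1": 14,
        "CDR2": 29,
        "CDR3": 53
      }
    }
  }
}
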