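{
  "scheme_id": "chothia-reconstructed-v1",
  "insertion_order": "ABCDEFGHIJKLMNOPQRSTUVWXYZ",
  "chains": {
    "heavy": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85, 86, 87, 88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99, 100, 101, 102, 103, 104, 105, 106, 107, 108, 109, 110, 111, 112, 113],
      "regions": {
        "FR1": [1, 25],
        "CDR1": [26, 32],
        "FR2": [33, 51],
        "CDR2": [52, 56],
        "FR3": [57, 94],
        "CDR3": [95, 102],
        "FR4": [103, 113]
      },
      "reentry": {
        "CDR1": 31,
        "CDR2": 52,
        "CDR3": 100
      }
    },
    "kappa": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85, 86, 87, 88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99, 100, 101, 102, 103, 104, 105, 106, 107],
      "regions": {
        "FR1": [1, 23],
        "CDR1": [24, 34],
        "FR2": [35, 49],
        "CDR2": [50, 56],
        "FR3": [57, 88],
        "CDR3": [89, 97],
        "FR4": [98, 107]
      },
      "reentry": {
        "CDR1": 30,
        "CDR2": 52,
        "CDR3": 95
      }
    },
    "lambda": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85, 86, 87, 88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99, 100, 101, 102, 103, 104, 105, 106, 107],
      "regions": {
        "FR1": [1, 23],
        "CDR1": [24, 34],
        "FR2": [35, 49],
        "CDR2": [50, 56],
        "FR3": [57, 88],
        "CDR3": [89, 97],
        "FR4": [98, 107]
      },
      "reentry": {
        "CDR1": 30,
        "CDR2": 52,
        "CDR3": 95
      }
    },
    "alpha": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85, 86, 87, 88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99, 100, 101, 102, 103, 104, 105, 106, 107],
      "regions": {
        "FR1": [1, 23],
        "CDR1": [24, 34],
        "FR2": [35, 49],
        "CDR2": [50, 56],
        "FR3": [57, 88],
        "CDR3": [89, 97],
        "FR4": [98, 107]
      },
      "reentry": {
        "CDR1": 30,
        "CDR2": 52,
        "CDR3": 95
      }
    },
    "beta": {
      "positions": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85, 86, 87, 88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99, 100, 101, 102, 103, 104, 105, 106, 107, 108, 109, 110, 111, 112, 113],
      "regions": {
        "FR1": [1, 25],
        "CDR1": [26, 32],
        "FR2": [33, 51],
        "CDR2": [52, 56],
        "FR3": [57, 94],
        "CDR3": [95, 102],
        "FR4": [103, 113]
      },
      "reentry": {
        "CDR1": 31,
        "CDR2": 52,
        "CDR3": 100
      }
    }
  }
}
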