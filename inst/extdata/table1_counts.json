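{
  "description": "Clinicopathological variable by subtype contingency tables transcribed from the source publication's association table. Columns are CMS1-like, CMS2-like, CMS3-like, CMS4-like. printed_p is the p-value as typeset in that table.",
  "columns": ["CMS1-like", "CMS2-like", "CMS3-like", "CMS4-like"],
  "variables": {
    "age": {
      "rows": ["<69", ">=69"],
      "counts": [[38, 93, 74, 28], [38, 75, 111, 24]],
      "printed_p": "0.027"
    },
    "sex": {
      "rows": ["Female", "Male"],
      "counts": [[41, 78, 83, 24], [35, 90, 102, 28]],
      "printed_p": "0.61"
    },
    "stage": {
      "rows": ["I", "II", "III", "IV"],
      "counts": [[9, 37, 37, 7], [25, 53, 52, 13], [27, 56, 63, 23], [15, 21, 33, 9]],
      "printed_p": "0.47"
    },
    "pT": {
      "rows": ["1", "2", "3", "4"],
      "counts": [[0, 10, 8, 2], [11, 35, 43, 8], [52, 110, 112, 35], [10, 11, 19, 7]],
      "printed_p": "0.249"
    },
    "pN": {
      "rows": ["0", "1", "2"],
      "counts": [[37, 93, 95, 22], [23, 47, 53, 11], [14, 26, 33, 19]],
      "printed_p": "0.064"
    },
    "pM": {
      "rows": ["0", "1"],
      "counts": [[61, 146, 152, 43], [15, 21, 30, 9]],
      "printed_p": "0.50"
    },
    "grade": {
      "rows": ["Low", "High"],
      "counts": [[57, 147, 158, 43], [15, 15, 18, 8]],
      "printed_p": "0.056"
    },
    "location": {
      "rows": ["Right colon", "Left colon", "Rectum"],
      "counts": [[46, 29, 54, 12], [10, 53, 45, 7], [20, 86, 86, 33]],
      "printed_p": "<0.001"
    },
    "histology": {
      "rows": ["Non-mucinous", "Mucinous"],
      "counts": [[59, 144, 148, 44], [11, 2, 12, 5]],
      "printed_p": "0.001"
    }
  }
}
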