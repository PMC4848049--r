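{
  "set1": {
    "provenance": "Epicardial right-ventricular lesion pattern, first survey: 6 contact-force measurements, 5 within the lesion pattern and 1 outside; MAP signals at 2 locations (B3 and D1) with maximal CFs of 7.3 and 8.9 grams; no MAPs at A4, B2, C1, C4, whose forces exceeded the mean viable-tissue CF but were not printed.",
    "printed_values": {
      "n_measurements": 6,
      "n_in_pattern": 5,
      "n_map_positive": 2,
      "map_positive_sites": ["B3", "D1"],
      "cf_g": {"B3": 7.3, "D1": 8.9},
      "map_negative_sites": ["A4", "B2", "C1", "C4"],
      "gap_site": "B3"
    }
  },
  "set2": {
    "provenance": "Same pattern after an additional RF application at B3: collection attempted at A1, B2, B3, C2 with no MAP detectable at B2 and B3; B2 silent even at 8.9 grams; A1 and C2 elicited MAPs but their forces were not printed. A1's pattern membership is not stated in the text; it is encoded out-of-pattern, consistent with the closing summary that the original gap no longer elicited MAPs.",
    "printed_values": {
      "map_negative_sites": ["B2", "B3"],
      "map_positive_sites": ["A1", "C2"],
      "cf_g": {"B2": 8.9}
    }
  },
  "set3": {
    "provenance": "Third survey, no further ablation, forces gradually increased beyond the mean required CF: B3 assessed with CFs up to 11 grams and no MAPs; A2 and C2 outside the pattern generated MAPs with peak forces of 11.57 and 11.96 grams; B2 silent at elevated CFs (value unprinted).",
    "printed_values": {
      "map_negative_sites": ["B3", "B2"],
      "map_positive_sites": ["A2", "C2"],
      "cf_g": {"B3": 11, "A2": 11.57, "C2": 11.96}
    }
  },
  "endocardial_mi": {
    "provenance": "Endocardial left-atrial mitral-isthmus linear lesion surveyed at 9 relative locations: no MAPs at locations 1, 4, 5 and 6 despite forces increased above 10 grams; MAPs recorded at the remaining 5 locations at CFs below 10 grams (exact values unprinted). MAP-positive locations are encoded as adjacent non-ablated myocardium (out-of-pattern), matching their reading as viable conductive tissue rather than gaps.",
    "printed_values": {
      "n_sites": 9,
      "map_negative_sites": ["1", "4", "5", "6"],
      "map_positive_sites": ["2", "3", "7", "8", "9"],
      "negative_min_cf_g": 10
    }
  }
}
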