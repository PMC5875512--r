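{
  "schema_version": "1.0",
  "protocols": [
    {
      "name": "Head and Neck",
      "site": "head",
      "kvp": 100,
      "ma_per_frame": 10,
      "ms_per_frame": 10,
      "frames": 361,
      "collimator": "S20",
      "start_deg": 70,
      "stop_deg": 270,
      "direction": "CW",
      "filter_id": "F0"
    },
    {
      "name": "Chest",
      "site": "chest",
      "kvp": 120,
      "ma_per_frame": 25,
      "ms_per_frame": 40,
      "frames": 650,
      "collimator": "M20",
      "start_deg": 270,
      "stop_deg": 270,
      "direction": "CW",
      "filter_id": "F0"
    },
    {
      "name": "Prostate",
      "site": "prostate",
      "kvp": 120,
      "ma_per_frame": 40,
      "ms_per_frame": 40,
      "frames": 650,
      "collimator": "M10",
      "start_deg": 270,
      "stop_deg": 270,
      "direction": "CW",
      "filter_id": "F0"
    }
  ]
}
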