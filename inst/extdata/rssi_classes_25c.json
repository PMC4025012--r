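{
  "classes": [
    {"name": "IV", "rssi_lo": 0, "rssi_hi": 60, "A": 0, "ratio": 1, "B": 0},
    {"name": "III", "rssi_lo": 61, "rssi_hi": 111, "A": 60, "ratio": 0.6, "B": 60},
    {"name": "II", "rssi_lo": 112, "rssi_hi": 143, "A": 112, "ratio": 0.3, "B": 112},
    {"name": "I", "rssi_lo": 144, "rssi_hi": 255, "A": 176, "ratio": 0.05, "B": 144}
  ]
}
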