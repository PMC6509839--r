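{
  "center_slash_padded": {
    "separator": "\\s*/\\s*",
    "sep_char": "/",
    "comment": "slashes with optional surrounding whitespace"
  },
  "center_semicolon_padded": {
    "separator": "\\s*;\\s*",
    "sep_char": ";",
    "comment": "semicolons with optional surrounding whitespace"
  }
}
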