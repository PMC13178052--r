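{
  "ambulatory_icds": {
    "prefixes": ["I21", "I25", "I42", "I48"],
    "ranges": [],
    "procedures": []
  },
  "ambulatory_procedures": {
    "prefixes": [],
    "ranges": [],
    "procedures": ["BNP", "ECHO", "CATH", "ERGO", "CHAGAS_SERO"]
  },
  "mortality": {
    "prefixes": ["B57", "I48", "I49", "I51"],
    "ranges": [["I05", "I08"], ["I21", "I25"], ["I34", "I39"], ["I42", "I44"]],
    "procedures": []
  },
  "subclass_ischaemic": {
    "prefixes": [],
    "ranges": [["I21", "I25"]],
    "procedures": []
  },
  "subclass_valvular": {
    "prefixes": [],
    "ranges": [["I05", "I08"], ["I34", "I39"]],
    "procedures": []
  },
  "subclass_cardiomyopathy": {
    "prefixes": ["B57"],
    "ranges": [["I42", "I44"]],
    "procedures": []
  },
  "subclass_other_cardiac": {
    "prefixes": ["I48", "I49", "I51"],
    "ranges": [],
    "procedures": []
  }
}
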