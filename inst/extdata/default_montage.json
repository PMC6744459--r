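{
  "version": 1,
  "comment": "Default 14-channel montage over six cortical regions (bilateral prefrontal, motor, occipital). The exact channel-to-region assignment is an assumption of this package: sources sit at the 10/10 sites Fp1/2, FC1/2, FC3/4, CP1/2, CP3/4 and detectors D1-D8 complete 10 sources + 8 detectors. Replace this file to change the assignment without touching code.",
  "inter_optode_distance_mm": 30,
  "dpf": 7.0,
  "wavelengths_nm": [740, 808, 850],
  "channels": [
    {"id": "CH01", "source": "Fp1", "detector": "D1", "region": "LPFC"},
    {"id": "CH02", "source": "FC1", "detector": "D1", "region": "LPFC"},
    {"id": "CH03", "source": "Fp2", "detector": "D2", "region": "RPFC"},
    {"id": "CH04", "source": "FC2", "detector": "D2", "region": "RPFC"},
    {"id": "CH05", "source": "FC3", "detector": "D3", "region": "LMC"},
    {"id": "CH06", "source": "CP3", "detector": "D3", "region": "LMC"},
    {"id": "CH07", "source": "CP1", "detector": "D5", "region": "LMC"},
    {"id": "CH08", "source": "FC4", "detector": "D4", "region": "RMC"},
    {"id": "CH09", "source": "CP4", "detector": "D4", "region": "RMC"},
    {"id": "CH10", "source": "CP2", "detector": "D6", "region": "RMC"},
    {"id": "CH11", "source": "CP1", "detector": "D7", "region": "LOC"},
    {"id": "CH12", "source": "CP3", "detector": "D7", "region": "LOC"},
    {"id": "CH13", "source": "CP2", "detector": "D8", "region": "ROC"},
    {"id": "CH14", "source": "CP4", "detector": "D8", "region": "ROC"}
  ]
}
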