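{
  "resource_version": "1.0",
  "comment": "Nine conserved sequence blocks of the tandem-FN2 (BSP superfamily) core. Coordinates are 1-based in the 87-position core frame anchored at the Block I cysteine. Patterns use the consensus notation: fixed residue letters, [..] alternative sets, x wildcard, h hydrophobic. block2_bsph1_pattern generalizes the terminal serine to other small residues for BSPH1 candidate scanning.",
  "hydrophobic": "AVLIMFWY",
  "blocks": [
    {"block_id": "I",    "domain": "FN2_1",  "pattern": "C[VA]FPFxY",          "canonical_start": 1,  "canonical_length": 7},
    {"block_id": "II",   "domain": "FN2_1",  "pattern": "C[TIV]xxxS",          "canonical_start": 15, "canonical_length": 6},
    {"block_id": "III",  "domain": "FN2_1",  "pattern": "xxWCSL[ND]",          "canonical_start": 22, "canonical_length": 7},
    {"block_id": "IV",   "domain": "FN2_1",  "pattern": "[YF]xG[YR]W[KR][YF]C","canonical_start": 31, "canonical_length": 8},
    {"block_id": "V",    "domain": "linker", "pattern": "xxD",                 "canonical_start": 40, "canonical_length": 3},
    {"block_id": "VI",   "domain": "FN2_2",  "pattern": "CxFPFh[YF]",          "canonical_start": 46, "canonical_length": 7},
    {"block_id": "VII",  "domain": "FN2_2",  "pattern": "GTxxG[SYDE]",         "canonical_start": 60, "canonical_length": 6},
    {"block_id": "VIII", "domain": "FN2_2",  "pattern": "hxxxWCSL[TS]",        "canonical_start": 67, "canonical_length": 9},
    {"block_id": "IX",   "domain": "FN2_2",  "pattern": "[YF][ND]xDxxW[KR][YQ]C", "canonical_start": 78, "canonical_length": 10}
  ],
  "block2_bsph1_pattern": "C[TIV]xxx[SAGT]",
  "fingerprints": {
    "BSPH1": {"III": "HKWCSLN", "VI": "ChFPFWY", "VIII": "FGKKWCSLT"},
    "BSPH2": {"IX": "YNxDxKWKQC", "V": "DPP", "IV": "FxGRWRYC", "CTER": "SP"}
  }
}
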