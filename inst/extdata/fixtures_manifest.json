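{
  "version": "1.0",
  "files": {
    "grid1471": "grid1471_synthetic.tsv",
    "montage62": "montage62_synthetic.tsv",
    "regions_fig5": "regions_fig5.tsv"
  },
  "md5": {
    "grid1471": "8215fe666217afe5d5c56682082c553b",
    "montage62": "202937dd3a53216ade6bbc4b4fe2fa7d",
    "regions_fig5": "68713d03d2c5946227509e27d2f3a162"
  }
}
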