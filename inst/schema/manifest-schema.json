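{
  "description": "Schema of manifest.json written next to every CLI output set.",
  "fields": {
    "subcommand": "string, producing command",
    "master_seed": "integer, all randomness derives from it",
    "config_hash": "string, hash of the canonical config serialisation (null when no config involved)",
    "package_version": "string",
    "created": "ISO 8601 timestamp",
    "outputs": "array of file names in the output directory"
  },
  "reproducibility": "re-running the subcommand with the recorded seed and config regenerates the outputs byte-identically"
}
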