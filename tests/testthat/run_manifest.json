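{
  "package": "hvblock",
  "package_version": "0.1.0",
  "r_version": "4.3.3",
  "timestamp": "2026-09-28T04:23:44+0000",
  "argv": [
    "no-such-command"
  ],
  "seed": null,
  "config": null,
  "status": "error",
  "error_code": "usage_error",
  "error_message": "unknown subcommand: no-such-command\nusage: hvblock <subcommand> [--config FILE] [--seed INT] [--out DIR]\n               [--input FILE] [--temperature-k K] [-v|-q]\nsubcommands:\n  simulate-dose | simulate-kinetics | simulate-state | simulate-scan\n  simulate-cycle | simulate-depletion\n  fit-dose | fit-kinetics | fit-gv | fit-partition\n  scan | cycle | report"
}
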