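{
  "title": "synthetic-42",
  "version": "1",
  "grid": {
    "extent": [0, 0, 10000, 10000],
    "resolution": 500,
    "crs": "EPSG:3035"
  },
  "pressures": [
    "pressure01",
    "pressure02"
  ],
  "layers": [
    {
      "name": "use01",
      "role": "use",
      "file": "layers/use01.asc"
    },
    {
      "name": "use02",
      "role": "use",
      "file": "layers/use02.asc"
    },
    {
      "name": "use03",
      "role": "use",
      "file": "layers/use03.asc"
    },
    {
      "name": "env01",
      "role": "env",
      "file": "layers/env01.asc"
    },
    {
      "name": "env02",
      "role": "env",
      "file": "layers/env02.asc"
    }
  ]
}
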