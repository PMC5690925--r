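body { font-family: "Helvetica Neue", Arial, sans-serif; margin: 2em; color: #222; }
h1 { border-bottom: 2px solid #444; padding-bottom: 0.2em; }
h2 { margin-top: 1.4em; color: #334; }
table { border-collapse: collapse; margin: 0.6em 0; }
th, td { border: 1px solid #bbb; padding: 0.25em 0.6em; text-align: left; font-size: 0.92em; }
th { background: #eef; }
tr.fail td { background: #fdd; font-weight: bold; }
tr.warn td { background: #ffedcc; }
.verdict.pass { color: #060; }
.verdict.fail { color: #a00; }
img.fluence { width: 180px; height: 180px; image-rendering: pixelated; border: 1px solid #999; margin-right: 6px; }
.capture img { max-width: 420px; border: 1px solid #999; }
.note { color: #666; font-style: italic; }
.footer { margin-top: 2em; color: #888; font-size: 0.85em; }
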