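# Qualifier triggers for negation / hypothesis / medical-history detection.
#
# ConText-style scoping: a qualifier fires when a trigger occurs in the same
# sentence as the mention, on the stated side (forward = trigger precedes the
# mention, backward = trigger follows it), within `scope` tokens between
# trigger and mention.  Patterns are matched case- and accent-insensitively
# on folded text, like lexicon patterns, but are NOT word-boundary wrapped
# (several end mid-word at an apostrophe).
negation:
  - {pattern: "pas d[e']", direction: forward, scope: 8}
  - {pattern: "absence d[e']", direction: forward, scope: 8}
  - {pattern: "aucun[e]?\\b", direction: forward, scope: 8}
  - {pattern: "\\bsans\\b", direction: forward, scope: 5}
  - {pattern: "\\bni\\b", direction: forward, scope: 5}
  - {pattern: "negati(f|ve) pour", direction: forward, scope: 8}
  - {pattern: "permet d'eliminer", direction: forward, scope: 8}
  - {pattern: "est exclu[e]?", direction: backward, scope: 6}
  - {pattern: "non retrouve[e]?", direction: backward, scope: 6}
hypothesis:
  - {pattern: "evoqu(e|ant|er)", direction: forward, scope: 8}
  - {pattern: "suspicion d[e']", direction: forward, scope: 8}
  - {pattern: "suspect[e]? d[e']", direction: forward, scope: 8}
  - {pattern: "\\bpossible\\b", direction: forward, scope: 6}
  - {pattern: "compatible avec", direction: forward, scope: 8}
  - {pattern: "pourrait correspondre a", direction: forward, scope: 8}
  - {pattern: "a confirmer", direction: backward, scope: 6}
  - {pattern: "\\bpossible\\b", direction: backward, scope: 4}
history:
  - {pattern: "antecedent[s]? d[e']", direction: forward, scope: 8}
  - {pattern: "atcd d[e']", direction: forward, scope: 8}
  - {pattern: "histoire d[e']", direction: forward, scope: 8}
  - {pattern: "ancien[ne]{0,2}\\b", direction: forward, scope: 5}
  - {pattern: "opere[e]? en (19|20)[0-9]{2}", direction: forward, scope: 8}
  - {pattern: "traite[e]? en (19|20)[0-9]{2}", direction: forward, scope: 8}
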