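# Seed pattern library for the four-tier rule classifier.
# Tiers are applied in this order; the first tier with a match decides.
# Patterns are Perl-compatible regular expressions matched against the
# lowercased raw snippet window.
absolute_positive:
  # enumerated problem-list entries, e.g. "5. opioid dependence"
  - '\b\d+\s*[.)]\s*(opioid|opiate) (dependence|abuse|use disorder)\b'
  # diagnosis with an inline ICD/SNOMED code, e.g. "opioid dependence (icd-9-cm 304.00)"
  - '(opioid|opiate) (dependence|abuse|use disorder)\s*\(\s*(icd|snomed)[-a-z0-9 .:]*\)'
  - 'continues? to struggle with (opioid|opiate|substance) (abuse|dependence|use)'
  # checked questionnaire box, tolerant of whitespace inside the brackets
  - '\[\s*x\s*\]\s*substance abuse and/?or dependence'
  - 'overuse of (opioid|opiate|pain) medication'
  - 'admitted? to abuse of (prescription )?(pain ?killers|opioids|opiates)'
canceling:
  - '\bformer (opioid|opiate|substance) (abuse|dependence|use)'
  - '\b(opioid|opiate|substance) (abuse|dependence)\W{0,3}in (full |sustained |early )?remission'
  - 'denie[sd] (any )?(current )?(opioid|opiate|substance) (abuse|misuse|use)'
  - 'no (evidence|history|hx) of (opioid|opiate|substance) (abuse|misuse|dependence)'
general_positive:
  - '\b(opioid|opiate) (abuse|dependence|addiction)\b'
  - '\bopioid use disorder\b'
  - '\bpolysubstance dependence\b'
neutral:
  # someone other than the patient
  - '\b(sister|brother|mother|father|son|daughter|spouse|husband|wife|cousin|uncle|aunt|friend) (abuses|abused|uses|used|is using|misuses)\b'
  - '\bfamily (hx|history) of\b'
  # allergy lists
  - '\ballerg(y|ies|ic)\s*(to\b|[:(])'
  # medication directions / medication-list lines
  - '\btake (one|two|\d+) (tablet|capsule|pill)'
  - '\bwhen needed for pain\b'
  - '\bq\s?\d+\s?-?\d*\s?h(r|rs|ours?)?\b'
  - '\bprn\b'
  - '\bgive:?\s*\d'
  - '\b\d+(\.\d+)?\s?mg\b[^|]*\b(tab|tablet|cap|capsule|soln|inj)\b'
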