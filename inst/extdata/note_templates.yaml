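# Templated clinical sentences used by the synthetic note generator.
# "{term}" is the slot for a lexicon term. Extend freely: the generator
# reads this file at run time.
neutral:
  - "Follow-up visit for hypertension management."
  - "Medication list reviewed and reconciled."
  - "Patient reports improved exercise tolerance."
  - "Discussed diet and statin adherence."
  - "No chest pain or dyspnea since last visit."
  - "Lipid panel reviewed; continue current regimen."
  - "Flu vaccine administered today."
positive:
  - "Patient reports smoking {term} most evenings."
  - "Endorses regular {term} use for sleep."
  - "Social history notable for {term} use."
  - "Uses {term} several times per week for chronic pain."
  - "{term} use discussed; patient declines cessation counseling."
negated:
  - "Patient denies {term} use."
  - "Denies any {term} or other recreational drug use."
  - "No {term} use reported this year."
historical:
  - "Remote history of {term} use in his twenties."
  - "Distant {term} use, quit decades ago."
confounder:
  - "Chronic TMJ pain with jaw clicking."
  - "Referred to dental clinic for TMJ evaluation."
  - "Discussed recent article on cannabinoid receptor signaling."
  - "Reviewed cannabidiol supplement question; none in use."
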