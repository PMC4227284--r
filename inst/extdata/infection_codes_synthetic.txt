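# Synthetic surrogate list of ICD-9 codes indicating infection on admission.
# This is NOT the validated list used by any published study; it is a small
# illustrative stand-in so that code-based inclusion can be exercised on
# synthetic cohorts. One code per line; trailing text after whitespace is a
# label and is ignored by the reader.
038.9   septicemia, unspecified
038.0   streptococcal septicemia
038.11  staphylococcus aureus septicemia
480.9   viral pneumonia, unspecified
481     pneumococcal pneumonia
482.9   bacterial pneumonia, unspecified
486     pneumonia, organism unspecified
590.10  acute pyelonephritis
595.0   acute cystitis
599.0   urinary tract infection, site not specified
567.9   peritonitis, unspecified
680.9   carbuncle and furuncle, unspecified site
682.9   cellulitis and abscess, unspecified site
711.00  pyogenic arthritis, site unspecified
730.20  unspecified osteomyelitis, site unspecified
790.7   bacteremia
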