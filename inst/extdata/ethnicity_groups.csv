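ethnicity_fine,ethnicity_broad
British,White
Irish,White
Any other White background,White
White and Black Caribbean,Mixed
White and Black African,Mixed
White and Asian,Mixed
Any other Mixed background,Mixed
Indian,Asian
Pakistani,Asian
Bangladeshi,Asian
Chinese,Asian
Any other Asian background,Asian
African,Black
Caribbean,Black
Any other Black background,Black
Arab,Other
Any other ethnic group,Other
Unknown,Unknown
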