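>hCx32syn|Homo sapiens|Cx32
MNWTGLYTLLSGVNRHSTAIGRVWLSVIFIFRIMVLVVAAESVWGDEKSSFICNTLQPGC
NSVCYDHFFPISHVRLWSLQLILVSTPALLVAMHVAHQQHIEKRMLRLEGHGDPLHLEES
VKRHKVHISGTLWWTYVISVVFRLLFEAVFMYVFYLLYPGYAMVRLVKCEAYPCPNTVDC
FVSRPTEKTVFTVFMLAASGICIILNVAEVVYLIIRACARRAQRRSNPPSRKGSGFGHRL
SPEYKQNEINKLLSEQDGSLKDILRRSPGTGAGLAEKSDRCSAC
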