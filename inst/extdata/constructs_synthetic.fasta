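>cmCx26|Chelonia mydas|Cx26
MDWGSLQTILGGVNKHSTSIGKIWLTVLFVFRIMILVVAAKEVWGDEQSDFVCNTLQPGC
KNVCYDHYFPISHIRLWALQLIFVSTPALLVAMHVAYRRHEKKRKFIKGEIKSDFKDIEE
IKTQKVRIEGSLWWTYTSSIFFRVIFEAAFMYVFYVMYDGFSMQRLVRCNAWPCPNTVDC
FVSRPTEKTVFTVFMIAVTGICILLNVTELCYLLIRYCSGKSKKPV
>gjCx26|Gekko japonicus|Cx26
MDWGTLQSILGGVNKHSTSIGKIWLTVLFIFRVMILVVAAKEVWGDEQADFVCNTLQPGC
KNVCYDHYFPISHIRLWALQLIFISTPALLVAMHVAYRRHEKKRKFIKGEIKSEFKDIEE
IKTQKVRIEGSLWWTYTSSVFFRVIFEAAFMYVFYVMYDGFSMQRLVKCNAWPCPNTVDC
FVSRPTDKTVFTVFMIAVSGICILLNVTELSYLLIRYCSGKSKKPV
>xtCx26|Xenopus tropicalis|Cx26
MDWGTLQTILGAVNKHSTSIGKIWLTVLFIFRIMILIVAAKEVWGDEQADFVCNTLQPGC
KNVCYDHYFPISHIRLWALQLIFVSTPALLIAMHVAYRRHEKKRKFIKGEIKSEFKDVEE
IKTQKVRIEGSLWWTYTSSIFFRVIFEAAFMFVFYVMYDGFSMQRLVKCNAWPCPNTVDC
FVSRPTEKTVFTVFMIAVSGICILMNVTELCYKSKKPVSENSVNKNIHSLRHSNQTSEKQ
DSSAHVTTSGNMEHFSDKVG
>lpCx26|Lepidosiren paradoxa|Cx26
MDWGTLQTILGGVNRHSTSIGKIWLTVLFIFRIMILVVAAKDVWGDEQADFVCNTLQPGC
KNVCYDHYFPISHIRLWALQLIFVSTPSLLVAMHVAYRRHEKKRKFIKGEVKSEFKDIEE
IKTQKVRIEGSLWWTYTSSIFFRVIFEAAFMYVFYVMYDGFSLQRLVKCNAWPCPNTVDC
FVSRPTEKTVFTVFMIAVSGVCILLNVTELCYKSKKPVLRHGKQEKYSSNQSSLMSKGKE
HQHSSRSDHYSV
>lcCx26s|Latimeria chalumnae|Cx26
MDWGTLQTIMGGVNKHSTSIGKIWLSVLFIFRIMILVVAAKEVWGDEQADFVCNSLQPGC
KNVCYDHYFPISHIRLWALQLIFVSTPALLVAMHVAYRRHEKRRKFIKGEIKSEFKDIEE
IKTQKVRIEGSLWWTYTSSIFFRVIFEAAFMYVFYVMYEGFSMQRLVKCNAWPCPNTVDC
YVSRPTEKTVFTVFMIAVSGICILLNVTELCYLLIRYCSGKSKKPV
>drCx32|Danio rerio|Cx32
MNWTGLFTLLSGVNRHSTAIGRVFLSVIFIFRIMVLVVAAESVWGDEKSSFICNTLQAGC
NSVCYDHFFPISHVRLWSLQLILVSTPALLVAMHVAHNQHIEKRMLRLEGHGDPLHLEES
VKRHKVHISGTLWWTYVISVVFRLLFEAVYMYVFYLLYPGYAMVRLVKCEAYPCPNTVDC
FVSRPTEKTVFTVFMLAASGICVILNVAEVVYLIIRACARRAQRRSNPPSRKGSGFGHRL
SPEYKQNEINKLLSEQDGSMKDILRRSPGTGAGLAEKSDRCSAC
>rtCx32|Rhincodon typus|Cx32
MNWTGLYTLLTGVNRHSTAIGRVWLSVIFIYRIMVLVVAAESVWGDEKSSFICNTLQPGC
NSVCYEHFFPISHVRLWSLQLILVSTPALLVAMHVAHQQHIEKRMLRLDGHGDPLHLEES
VKRHKVHISGTLWWTYVISVVFRLLFEAVFMYVFYLLYPGFAMVRLVKCEAYPCPNTVDC
FVSRPTEKTVFTVFMLAASGICIILNVAEVVYLIVRACARRAQRRSNPPSRKGSGFGHRL
SPEYKQNEINKLLSDQDGSLKDILRRSPGTGAGLAEKSDRCSAC
>pmCx27.5|Petromyzon marinus|Cx27.5
MDWGTMQTILGGVNKHSTSIGRIWLTVLFIFRIMILVVAAKEVWADEQADFVCNTLQPGC
KNVCYDHYFAISHIRLWALQLIFVSTPALLVALHVAYRRHEKKRKFIKGEIKSEFKDIEE
IKPPKVRIEGTLWWTYTSSIFFRVIFEASFMYVFYVMYDGFSMQRLVKCNAWACPNTVDC
FVSRPTEKSVFTVFMIAVSGICILLNVTEMCYLLIRYCSGKSKKPVSGKTSESHRNDAQS
SKGNLEATSKHDSSVF
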