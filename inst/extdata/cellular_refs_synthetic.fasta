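>actin_like_synthetic
MRLFVPAIKRAWSSPQPRLEKTGYVPPQFLNDNFIIPVSDFLDPGQGNFMNGYASAPFAT
IGAIHIFSSPVPNPRGNYMTPHFTVSSIGKNLMVIHNIRVQDLMRGNNDTLSLMIMLRFD
DGTDHCMSAIRYAAKMNPPWLLSEYATFLIDDAINFIRYPFLFTLLAHAGRKYDEQVYFL
QQSDHPLLDAEIIEVPLRSQLTKFLHAMSL
>ef1a_like_synthetic
MSRYGLLDLILVADKLTAKPTPDVFLIRREGGLFEADIPDSPFTVNPDFLNVPGVALHSQ
LEDREHRKDGDLNGNYVDKTFKSVAGIKIYFSSGVTSLSNYAGDSDDPFHSLDNTTISGA
YLDSLMKKRLKRRGATSDVRNGAWEIVPHAQVCDVYNPKSLDSVYFDPVTTVLIHSAVED
KLQEEKYPLD
>gapdh_like_synthetic
MNKEHDKALLQGVEVTSGAYGQIVEQGAGAIDFYLLVQQVVLNTLFKLETILQRQSLGKF
TEGTSTDMANVNATRRGPAAKVNGSLAIPGRDEELVFLSLDRTYELFTEDQELEKAGQTA
LPASDITENLRPTRNYSELAAALVHVKGVQFQMGAPTPVGGVGEVKRYNV
>rpl7_like_synthetic
MILININELGTHDLPGFITSIWHMKELFTFLDYGGHRDEGGKYKLVSFNINREKIQGQKT
RHLKDKWMEGSNIFHQSNKGTTYKKERFPQALPIRDGKAENAPLEKNFRFNLIIRIVSEK
FVTIGKGLTSPKVANPRIEK
>hsp70_like_synthetic
MIGHEIHDAPRACEVLKLHNPGLIFHPLVADWDVSEAEVHDDNIMNAISRTVQEQEWDDD
QLASRKVVAKFNNGHARRGSDVNLTLPAFAELSMMERSITILISGDARGSFWSGDRGTGG
TKAVLVMKSTAYLSRRSGFNFSVKVTLTHSDREQALRRKKLSTLAVPVFLRPQYAERHAQ
RHMKLSAPVERLADELIIEVRKPSGAWLETPFTAEAADPSVDPIPSAKIS
>tubulin_like_synthetic
MVWDDDLRPEALWSLDLAESEGLPDGMWAVKTLTRGPLPRLLTIVKIAKWGLQHPKDGHF
LKHLISDGSLLVKKKIGARKGLLRNNQLLHGKLVACSYFSRKSFYNFQGTVGPDAIVLRK
ASANRKNLTDTTLFLIGMKVVKRGLPHVKWSAGLNALEMRATGDGHTVYRQGFEELKAQK
DEGYVKAMLAQFMFMNIIRT
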