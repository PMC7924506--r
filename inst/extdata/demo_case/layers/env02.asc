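ncols 20
nrows 20
xllcorner 0
yllcorner 0
cellsize 500
NODATA_value -9999
0.16920133403372245 0.3173957027546303 0.3400334230585107 0.31153090070455608 0.29856801717784248 0.35436168971669879 0.455795777342485 0.49995128663628846 0.46777768876985537 0.46236414178381297 0.52769966126629231 0.5848877774095872 0.58206141448932225 0.5425484966200913 0.51986115056203952 0.55154065003383179 0.57215701939291896 0.49320527514830392 0.34316281218719707 0.1548791128677299
0.28738095694797477 0.49688437294449678 0.5849466625574733 0.59378170682558484 0.59078154293380014 0.66130208158893033 0.78263681529965023 0.82173607257585823 0.75121511424154674 0.70202607062812483 0.72920080822175015 0.75430994207987523 0.74235841676615222 0.71226149393569438 0.69490892602720278 0.72844681212975793 0.76657435423189912 0.71601885310909985 0.57342269330220852 0.34624505443853881
0.2313598444040923 0.4675249195603598 0.62675765725451993 0.70618333273398448 0.74790327133422474 0.83238880554265837 0.94046064799167095 0.95968882720211146 0.8671976802476915 0.78070349860191013 0.74345512685801418 0.69384028419983013 0.63930737286370154 0.60574387951119779 0.59643910194786598 0.6411399844592981 0.71761066028036913 0.72998274611067737 0.62094706985360859 0.37852706630055927
0.17288071658301152 0.40458062846843584 0.58328621257147439 0.70564958280559831 0.79373517500155522 0.89068958373656049 0.97763865769916181 0.99328875843056796 0.92577829939694289 0.84749635264127454 0.77768922687836439 0.66904806149673013 0.55787779416948213 0.49362782192257149 0.48105570019153793 0.53942815362120811 0.64938674127988505 0.7093149224962727 0.61961098512511215 0.3578964367057792
0.23330670488588473 0.46559241880226837 0.61633103703278147 0.71567299300107823 0.79584675526463955 0.87691167384758995 0.93710620354150398 0.95394307633096975 0.92913394281176187 0.89154711472494286 0.83953446849653712 0.72950916613154426 0.58986604051725167 0.49367347113092491 0.46767755531011418 0.51642533684572389 0.62107194078685679 0.70011158614753444 0.63730687178018897 0.37335745478802956
0.34724053065828669 0.61973047115914692 0.75371669706212951 0.79198821616257609 0.80853074157911753 0.83928289510900533 0.8519814847179451 0.83641224338856424 0.82317193480678041 0.82732816767931128 0.82367260370115847 0.75484840597031533 0.62085363807574068 0.50526480124207174 0.45729212156688531 0.46956550735182107 0.53003639897351063 0.59877685798457514 0.56932905950513701 0.33953056188443353
0.38580769138362087 0.71442336997694611 0.86466133267537559 0.86050910239533029 0.82222967555414317 0.80850456336223309 0.76826148455703258 0.69820090111360877 0.67334414881270166 0.71768529438088324 0.76850122276906874 0.73772022062550691 0.6080472794346834 0.46792904573843125 0.39366921231900487 0.38213788281281291 0.40731992278706963 0.44410681967121574 0.41240483849354842 0.21574120964806387
0.34350752709441551 0.69632008926076228 0.86663662524484997 0.87173340843781355 0.84899618355344419 0.84138791087586839 0.77901481132664196 0.67542591876588554 0.63709640910251908 0.69589029801820634 0.75929662357313621 0.72086302942011504 0.57480738297394907 0.41717696723132797 0.34567296380420859 0.36529791100516135 0.408634934130501 0.41839637896167192 0.33751877168419064 0.12524002105816831
0.32748711733012775 0.67039318773886436 0.83364207295100556 0.86147855460908285 0.88523364382027492 0.91259641988111906 0.86902489911557979 0.78024897450599207 0.73609532532863509 0.75445446566701757 0.76168860486267775 0.68590350813845369 0.53777697224167276 0.3975076291036384 0.36048963023967673 0.43996590910333555 0.53277708931061041 0.53192335496431087 0.39350271660256764 0.13677357560604902
0.36802482855605956 0.68918766020468458 0.81976554530103818 0.83473562738061724 0.86269394329157334 0.90754708455634647 0.90819212910062208 0.88231914813891499 0.85782288535087092 0.8081858283384038 0.72401991905157548 0.6288892861305283 0.52953336448079336 0.43894541432239148 0.43118474577100463 0.54104497017865039 0.65706845390869206 0.64891931368765676 0.49109463692067645 0.21823644199012845
0.39142493139497631 0.69898501151979231 0.80951611773394194 0.79930906544417879 0.80303925896434036 0.85061244273083603 0.89258639459248812 0.93271412114398067 0.94578941092512581 0.84799655216024694 0.6811759191989003 0.58305612888288472 0.56111556485565328 0.53546681225341786 0.54094575750297846 0.63964531468360131 0.74263863157480903 0.73903471017582023 0.61552657658226639 0.35868044546015271
0.36102172269327004 0.67939758345293666 0.80989727675671352 0.79739091922289107 0.78301165237219772 0.82535718868312535 0.88184013376873682 0.9552142645595697 1 0.88923726185743013 0.67179541420884203 0.55985003116475707 0.58702150792403707 0.61115115718337887 0.61610923922266336 0.68385034897254926 0.77984326275509752 0.82982386907473027 0.78496842309696868 0.54244253851179858
0.28361799917866598 0.63003425453793949 0.81622866975704389 0.82782306953402329 0.79370552907111314 0.80353782116099715 0.84746356091409647 0.93505805139780362 0.99657059122270486 0.88824719491013904 0.660910091275282 0.54150829207339057 0.5826915331227287 0.63189736664797269 0.63462301129865761 0.67605356859265386 0.78151076918763684 0.90531109338562099 0.93353136025554251 0.68609217689490187
0.1765202776146097 0.54859290728535282 0.80919863984008855 0.86818166419790732 0.80696305711074234 0.74764354829505963 0.7514536248322744 0.84153621633743747 0.90581185873235015 0.80123893442157024 0.60561451436665148 0.52378894771669005 0.59087928600634654 0.66733479440407584 0.67994542438614602 0.70227313795460933 0.79957634131599875 0.94197259884151074 0.97428748959091338 0.69992054093997269
0.1137611039862646 0.48102842247631405 0.77525040473978313 0.86999054444920509 0.78835641313171712 0.66404836765885777 0.62840909104748321 0.71564291123698842 0.77760848032069496 0.68785140203573092 0.55318306848814369 0.53635603564813605 0.63689984171281289 0.73278448637159255 0.74754362549952991 0.74540578115594724 0.81540992313828076 0.92532088232644305 0.89803221594106253 0.57939853485999904
0.12982397780537272 0.4338290679308992 0.66790908264363835 0.74964281582605941 0.67475912367417112 0.55661032589685677 0.54182264646917 0.64460417282998272 0.70811356037677808 0.65334091858488852 0.58929522465474904 0.61056967880782798 0.69483732916075325 0.76842880479436859 0.77466012296492592 0.75447068133062711 0.79131997081112815 0.85217812989233876 0.75762881195701182 0.40597487697390988
0.17368361007742375 0.38199366443446542 0.50820919192630565 0.55800242836288505 0.52348108376882152 0.47241963050365099 0.52054564414759952 0.64653217313891531 0.7154808263303073 0.71456337544671866 0.72249269990206788 0.74128224638870199 0.74558733260465038 0.76109230634662639 0.78194545671979609 0.77898640399591423 0.77207135793968429 0.75621901358788102 0.61038225921712619 0.26616029651183898
0.22404845731053036 0.36709149874420194 0.41567774652923944 0.45698727126962169 0.47358160427882817 0.47314795187187975 0.54581038911700064 0.66979071174397276 0.75046650245797253 0.813375872436509 0.87862711717338116 0.8651205750609019 0.76513826633358051 0.71642633308188586 0.77501639967787384 0.82906241055058383 0.79684600498522418 0.69274488603131656 0.49779674854007433 0.18479318358107258
0.24815363366743676 0.36751921475489913 0.37906967575661443 0.41713032027598151 0.45792608128652451 0.46168475787770302 0.50703772766618438 0.60738012621007009 0.7097281251268861 0.8277143926332915 0.91594020852635949 0.85842720590940247 0.6818654448984216 0.58412602741845743 0.65790463909936037 0.764775340115322 0.75179925206506215 0.61004244759320747 0.39232033200130828 0.12137095133225574
0.13407734383933859 0.23170491222604975 0.22842634221522928 0.24827958200457945 0.2778066146011362 0.27007385850786497 0.28493844275414282 0.35909672225704825 0.46758863333403949 0.59402156234777015 0.6648817155256963 0.5860918488458039 0.40604478572613772 0.30048475748128634 0.35456025418475556 0.46405460715004931 0.48011678502342864 0.36947357925258217 0.19611596022902519 0
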